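#' Statistical policy for group comparisons
#'
#' Encodes the normality-gated testing scheme used throughout the package:
#' each group is tested for normality (Shapiro-Wilk) on the raw and the log
#' scale; if every group passes on at least one common scale at `alpha`, the
#' parametric branch is used (two-sided t test, or one-way ANOVA with Tukey's
#' HSD for three or more groups), otherwise the nonparametric branch
#' (two-sided Mann-Whitney U, or Kruskal-Wallis with Dunn's post hoc test).
#' The policy and the per-group normality p-values are recorded in every
#' result for auditability.
#'
#' @param alpha significance level for both the normality gate and the tests
#'   (default 0.05).
#' @param branch `"auto"` (normality-gated), `"parametric"`, or
#'   `"nonparametric"` to force a branch.
#' @param posthoc_adjust multiplicity adjustment for Dunn's pairwise
#'   p-values: `"holm"` (default), `"bonferroni"`, or `"none"`.
#' @param shapiro_max Shapiro-Wilk sample-size cap; larger groups are
#'   subsampled (deterministically) to this size for the gate.
#' @return list of class `test_policy`.
#' @export
test_policy <- function(alpha = 0.05,
                        branch = c("auto", "parametric", "nonparametric"),
                        posthoc_adjust = c("holm", "bonferroni", "none"),
                        shapiro_max = 5000L) {
  structure(list(alpha = alpha, branch = match.arg(branch),
                 posthoc_adjust = match.arg(posthoc_adjust),
                 shapiro_max = as.integer(shapiro_max)),
            class = "test_policy")
}

# Shapiro-Wilk p-value; subsample deterministically above the cap.
shapiro_p <- function(x, cap) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) return(NA_real_)
  if (length(x) > cap) x <- x[round(seq(1, length(x), length.out = cap))]
  if (sd(x) == 0) return(0)   # degenerate: certainly not normal
  shapiro.test(x)$p.value
}

# Decide the branch; returns list(branch, gate) where gate records the
# per-group raw/log Shapiro p-values.
gate_branch <- function(groups, policy) {
  gate <- lapply(groups, function(g) {
    c(raw = shapiro_p(g, policy$shapiro_max),
      log = if (all(g > 0)) shapiro_p(log(g), policy$shapiro_max) else NA_real_)
  })
  if (policy$branch != "auto")
    return(list(branch = policy$branch, gate = gate, forced = TRUE))
  ns <- lengths(groups)
  if (any(ns < 3L)) {
    warning("group(s) with n < 3: normality cannot be assessed; ",
            "using the nonparametric branch")
    return(list(branch = "nonparametric", gate = gate, forced = FALSE))
  }
  raw_ok <- all(vapply(gate, function(g) isTRUE(g["raw"] > policy$alpha),
                       logical(1)))
  log_ok <- all(vapply(gate, function(g) isTRUE(g["log"] > policy$alpha),
                       logical(1)))
  list(branch = if (raw_ok || log_ok) "parametric" else "nonparametric",
       gate = gate, forced = FALSE)
}

group_summaries <- function(groups, branch) {
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (branch == "parametric") {
      data.frame(group = names(groups)[i], n = length(g), mean = mean(g),
                 sem = sd(g) / sqrt(length(g)),
                 median = median(g), iqr_low = unname(quantile(g, 0.25)),
                 iqr_high = unname(quantile(g, 0.75)))
    } else {
      data.frame(group = names(groups)[i], n = length(g), mean = mean(g),
                 sem = sd(g) / sqrt(length(g)),
                 median = median(g), iqr_low = unname(quantile(g, 0.25)),
                 iqr_high = unname(quantile(g, 0.75)))
    }
  }))
}

#' Two-group comparison with a normality gate
#'
#' Chooses a two-sided unpaired t test or a two-sided Mann-Whitney U test via
#' the policy's normality gate. In the rank branch the exact U-distribution
#' p-value is used when `min(n) <= 8` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @param policy a [test_policy()].
#' @param labels group labels for the report.
#' @return object of class `group_comparison`: test name, statistic, p-value,
#'   per-group summaries (median/IQR and mean/SEM), the branch taken and the
#'   normality p-values behind it.
#' @examples
#' compare_two(rnorm(20), rnorm(20, 1), test_policy())
#' @export
compare_two <- function(a, b, policy = test_policy(),
                        labels = c("A", "B")) {
  if (!length(a) || !length(b)) stop("empty group")
  groups <- setNames(list(as.numeric(a), as.numeric(b)), labels)
  gb <- gate_branch(groups, policy)
  if (gb$branch == "parametric") {
    ht <- t.test(a, b)
    test <- "Welch two-sided t test"
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- min(length(a), length(b)) <= 8 && !ties
    if (min(length(a), length(b)) <= 8 && ties)
      warning("ties present; falling back to the tie-corrected normal ",
              "approximation")
    ht <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = !exact))
    test <- paste0("Mann-Whitney U test (",
                   if (exact) "exact" else "normal approximation", ")")
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 branch = gb$branch, normality = gb$gate,
                 alpha = policy$alpha,
                 summaries = group_summaries(groups, gb$branch),
                 posthoc = NULL),
            class = "group_comparison")
}

#' Multi-group comparison with matching post hoc table
#'
#' Three or more groups: one-way ANOVA followed by Tukey's HSD (parametric
#' branch) or Kruskal-Wallis followed by Dunn's test with tie-corrected rank
#' variance (nonparametric branch), gated exactly as in [compare_two()].
#' Post hoc p-values are multiplicity-adjusted per the policy and the
#' adjustment is named in the table.
#'
#' @param groups named list of numeric samples (>= 3 groups).
#' @param policy a [test_policy()].
#' @return a `group_comparison` with a `posthoc` pairwise table.
#' @export
compare_many <- function(groups, policy = test_policy()) {
  if (length(groups) < 3L) stop("`compare_many` needs >= 3 groups")
  if (any(!lengths(groups))) stop("empty group")
  if (is.null(names(groups)))
    names(groups) <- paste0("G", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  gb <- gate_branch(groups, policy)
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (gb$branch == "parametric") {
    fit <- aov(values ~ glab)
    an <- summary(fit)[[1]]
    test <- "one-way ANOVA"
    stat <- an[["F value"]][1]
    p <- an[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$glab
    pairs <- rownames(tk)
    posthoc <- data.frame(
      comparison = pairs, estimate = tk[, "diff"],
      p_adjusted = tk[, "p adj"], method = "Tukey HSD",
      row.names = NULL)
  } else {
    kw <- kruskal.test(values, glab)
    test <- "Kruskal-Wallis rank sum test"
    stat <- unname(kw$statistic)
    p <- kw$p.value
    posthoc <- dunn_test(values, glab, adjust = policy$posthoc_adjust)
  }
  structure(list(test = test, statistic = stat, p_value = p,
                 branch = gb$branch, normality = gb$gate,
                 alpha = policy$alpha,
                 summaries = group_summaries(groups, gb$branch),
                 posthoc = posthoc),
            class = "group_comparison")
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie-corrected rank variance:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups. Two-sided p-values are
#' multiplicity-adjusted over all pairs.
#'
#' @param values numeric vector of all observations.
#' @param groups factor (or coercible) of group membership.
#' @param adjust `"holm"` (default), `"bonferroni"`, or `"none"`.
#' @return data frame: `comparison`, `z`, `p_unadjusted`, `p_adjusted`,
#'   `method`.
#' @export
dunn_test <- function(values, groups, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  rb <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- t(combn(length(lev), 2))
  z <- (rb[pairs[, 1]] - rb[pairs[, 2]]) /
    sqrt(v0 * (1 / ns[pairs[, 1]] + 1 / ns[pairs[, 2]]))
  z <- unname(z)
  p <- 2 * pnorm(-abs(z))
  p[is.nan(p)] <- 1                    # all-tied data: zero variance
  padj <- if (adjust == "none") p else p.adjust(p, method = adjust)
  data.frame(comparison = paste(lev[pairs[, 1]], "-", lev[pairs[, 2]]),
             z = z, p_unadjusted = p, p_adjusted = pmin(padj, 1),
             method = paste0("Dunn (", adjust, ")"))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g [%s branch]\n",
              x$test, x$statistic, x$p_value, x$branch))
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    if (x$branch == "parametric")
      cat(sprintf("  %s: n = %d, mean = %.4g +/- %.3g SEM\n",
                  s$group[i], s$n[i], s$mean[i], s$sem[i]))
    else
      cat(sprintf("  %s: n = %d, median = %.4g [IQR %.4g-%.4g]\n",
                  s$group[i], s$n[i], s$median[i], s$iqr_low[i], s$iqr_high[i]))
  }
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
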
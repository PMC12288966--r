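#' Long axis of a single 2D nuclear mask
#'
#' Finds the principal direction of the mask's pixel coordinates (in um) and
#' returns a measurement segment through the centroid along it, extended past
#' the mask by `overshoot_um` on each side so that the nuclear edges are
#' sampled. For nearly isotropic masks (aspect ratio within `tie_tol` of 1)
#' the direction is tied to the image x-axis.
#'
#' @param mask logical matrix (single connected component).
#' @param pixel_size um per pixel, `c(dx, dy)`.
#' @param overshoot_um extension beyond the mask at each end (default 2 um).
#' @param tie_tol relative eigenvalue gap below which the axis is considered
#'   degenerate (a circle) and the x-axis is used.
#' @return list with `start`, `end` (um), `center`, `direction` (unit vector),
#'   `chord_um` (in-mask extent along the axis).
#' @export
long_axis <- function(mask, pixel_size, overshoot_um = 2, tie_tol = 1e-3) {
  if (!is.logical(mask) || length(dim(mask)) != 2L)
    stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("empty mask")
  ncomp <- max(cc_label_cpp(as.logical(mask), dim(mask), FALSE))
  if (ncomp > 1L) stop("mask has ", ncomp, " components; expected one nucleus")
  pc <- which(mask, arr.ind = TRUE)
  xy <- sweep(pc - 0.5, 2, pixel_size, `*`)
  ctr <- colMeans(xy)
  cxy <- sweep(xy, 2, ctr)
  ev <- eigen(crossprod(cxy) / nrow(cxy), symmetric = TRUE)
  dirv <- ev$vectors[, 1]
  if ((ev$values[1] - ev$values[2]) <= tie_tol * ev$values[1])
    dirv <- c(1, 0)
  if (dirv[1] < 0 || (dirv[1] == 0 && dirv[2] < 0)) dirv <- -dirv
  proj <- cxy %*% dirv
  tmin <- min(proj); tmax <- max(proj)
  half_px <- sum(abs(dirv) * pixel_size) / 2   # pixel extent along the axis
  tmin <- tmin - half_px; tmax <- tmax + half_px
  list(start = ctr + (tmin - overshoot_um) * dirv,
       end = ctr + (tmax + overshoot_um) * dirv,
       center = ctr, direction = dirv,
       chord_um = tmax - tmin)
}

#' Sample an intensity profile along a segment (middle z-plane)
#'
#' Bilinearly interpolates the channel at uniform steps along the segment.
#' For a 3D channel the middle z-plane is used; for a 2D channel the plane
#' itself. When a nuclear `mask` is supplied, the positions where the segment
#' crosses the mask boundary are recorded as the nuclear edges.
#'
#' @param channel a [voxel_grid].
#' @param segment list with `start` and `end` in um (see [long_axis()]).
#' @param step sampling step in um (default 0.1).
#' @param mask optional logical matrix, the nucleus mask on the sampled plane.
#' @return object of class `line_profile`: `positions` (um along the
#'   segment), `intensities`, `edge_positions` `c(p_left, p_right)` (or
#'   `NULL` without a mask), `z_plane`.
#' @export
sample_profile <- function(channel, segment, step = 0.1, mask = NULL) {
  stopifnot(inherits(channel, "voxel_grid"))
  if (step <= 0) stop("`step` must be positive")
  dims <- dim(channel)
  vs <- channel$voxel_size
  if (length(dims) == 3L) {
    z_plane <- (dims[3] + 1L) %/% 2L
    plane <- channel$intensities[, , z_plane]
  } else {
    z_plane <- 1L
    plane <- channel$intensities
  }
  a <- segment$start[1:2]
  b <- segment$end[1:2]
  len <- sqrt(sum((b - a)^2))
  dirv <- (b - a) / len
  positions <- seq(0, len, by = step)
  pts <- cbind(a[1] + positions * dirv[1], a[2] + positions * dirv[2])
  ext <- dim(plane) * vs[1:2]
  if (any(pts < 0) || any(pts[, 1] > ext[1]) || any(pts[, 2] > ext[2]))
    stop("segment exits the image (extent ",
         paste(signif(ext, 4), collapse = " x "), " um)")
  intensities <- bilinear_at(plane, vs[1:2], pts)
  edges <- NULL
  if (!is.null(mask)) {
    mi <- bilinear_at(mask * 1, vs[1:2], pts) >= 0.5
    if (any(mi)) {
      inside <- which(mi)
      edges <- c(positions[inside[1]], positions[inside[length(inside)]])
    }
  }
  structure(list(positions = positions, intensities = intensities,
                 edge_positions = edges, z_plane = z_plane, step = step),
            class = "line_profile")
}

# Bilinear interpolation at physical points; pixel centres at (i-0.5)*h.
# Points beyond the outermost centres clamp to the edge value.
bilinear_at <- function(plane, h, pts) {
  u <- pts[, 1] / h[1] + 0.5
  v <- pts[, 2] / h[2] + 0.5
  nx <- nrow(plane); ny <- ncol(plane)
  u <- pmin(pmax(u, 1), nx)
  v <- pmin(pmax(v, 1), ny)
  i0 <- pmin(floor(u), nx - 1L); j0 <- pmin(floor(v), ny - 1L)
  fu <- u - i0; fv <- v - j0
  p00 <- plane[cbind(i0, j0)]
  p10 <- plane[cbind(i0 + 1, j0)]
  p01 <- plane[cbind(i0, j0 + 1)]
  p11 <- plane[cbind(i0 + 1, j0 + 1)]
  p00 * (1 - fu) * (1 - fv) + p10 * fu * (1 - fv) +
    p01 * (1 - fu) * fv + p11 * fu * fv
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.2f um%s\n",
              length(x$positions), max(x$positions),
              if (!is.null(x$edge_positions))
                sprintf(", nucleus [%.2f, %.2f] um", x$edge_positions[1],
                        x$edge_positions[2]) else ""))
  invisible(x)
}

# Trapezoidal integral of the sampled profile over [a, b], with linear
# interpolation at the interval endpoints (partial end intervals).
trapz_interval <- function(positions, intensities, a, b) {
  if (b <= a) return(0)
  a <- max(a, positions[1]); b <- min(b, positions[length(positions)])
  if (b <= a) return(0)
  inner <- positions > a & positions < b
  xs <- c(a, positions[inner], b)
  ys <- c(approx(positions, intensities, a)$y,
          intensities[inner],
          approx(positions, intensities, b)$y)
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Peripheral-enrichment fraction of a line profile
#'
#' The share of the profile's signal lying within `d` um of the nuclear
#' edges: integral of intensity over
#' `[p_left, p_left + d] U [p_right - d, p_right]` divided by the integral
#' over the nuclear span `[p_left, p_right]` (trapezoidal rule, with linear
#' interpolation for partial end intervals). By default signal outside the
#' nuclear span is excluded from the denominator;
#' `denominator = "full"` uses the whole sampled segment instead. A nuclear
#' span `<= 2 d` makes the two margins cover the span; the fraction is then
#' trivially 1 and flagged.
#'
#' @param profile a [line_profile] with `edge_positions`.
#' @param d margin in um (default 3, the usual line-scan margin).
#' @param denominator `"span"` (default) or `"full"`.
#' @return list of class `peripheral_fraction`: `value` in \[0, 1\],
#'   `margin_um`, `span_um`, `flagged`.
#' @export
peripheral_fraction <- function(profile, d = 3,
                                denominator = c("span", "full")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(profile, "line_profile"))
  if (d <= 0) stop("`d` must be positive")
  if (is.null(profile$edge_positions))
    stop("profile has no nuclear edge positions; sample with a mask")
  p <- profile$positions
  y <- profile$intensities
  pl <- profile$edge_positions[1]
  pr <- profile$edge_positions[2]
  span <- pr - pl
  denom <- if (denominator == "span") trapz_interval(p, y, pl, pr) else
    trapz_interval(p, y, p[1], p[length(p)])
  if (denom <= 0) stop("no signal on line")
  flagged <- span <= 2 * d
  num <- if (flagged) trapz_interval(p, y, pl, pr) else
    trapz_interval(p, y, pl, pl + d) + trapz_interval(p, y, pr - d, pr)
  structure(list(value = num / denom, margin_um = d, span_um = span,
                 flagged = flagged),
            class = "peripheral_fraction")
}

#' @export
print.peripheral_fraction <- function(x, ...) {
  cat(sprintf("peripheral fraction = %.3f (margin %g um, span %.2f um)%s\n",
              x$value, x$margin_um, x$span_um,
              if (x$flagged) " [flagged: span <= 2d]" else ""))
  invisible(x)
}

#' Lane densitometry: area under a band profile
#'
#' Trapezoidal area of a 1D lane profile above a background baseline:
#' `"zero"` (no subtraction), `"min"` (subtract the profile minimum), or
#' `"linear"` (subtract the straight line joining the first and last
#' samples). Negative excursions after subtraction are clipped to zero.
#' Supplying a control lane yields the loading-normalised value
#' `auc / control_auc`.
#'
#' @param intensities lane profile values.
#' @param positions sample positions (default unit spacing).
#' @param background `"zero"`, `"min"`, or `"linear"`.
#' @param control optional control-lane intensities (same positions),
#'   processed with the same background mode.
#' @return list of class `lane_densitometry`: `auc`, `normalized` (or `NA`),
#'   `background`.
#' @export
lane_auc <- function(intensities, positions = NULL,
                     background = c("zero", "min", "linear"),
                     control = NULL) {
  background <- match.arg(background)
  if (!length(intensities)) stop("empty lane profile")
  if (is.null(positions)) positions <- seq_along(intensities) - 1
  auc <- one_lane_auc(intensities, positions, background)
  normalized <- NA_real_
  if (!is.null(control)) {
    cauc <- one_lane_auc(control, positions, background)
    if (cauc <= 0) stop("control lane AUC is zero; cannot normalise")
    normalized <- auc / cauc
  }
  structure(list(auc = auc, normalized = normalized, background = background),
            class = "lane_densitometry")
}

one_lane_auc <- function(y, x, background) {
  base <- switch(background,
                 zero = rep(0, length(y)),
                 min = rep(min(y), length(y)),
                 linear = seq(y[1], y[length(y)], length.out = length(y)))
  yy <- pmax(y - base, 0)
  sum(diff(x) * (head(yy, -1) + yy[-1]) / 2)
}

#' @export
print.lane_densitometry <- function(x, ...) {
  cat(sprintf("lane AUC = %.4g (background: %s)%s\n", x$auc, x$background,
              if (!is.na(x$normalized))
                sprintf(", normalised = %.4g", x$normalized) else ""))
  invisible(x)
}

#' Normalise a decay course to its t = 0 level per replicate
#'
#' @param course data frame with `replicate`, `time_h`, `level` (e.g. from
#'   [make_decay_course()]).
#' @return the course with `level` divided by each replicate's t = 0 level.
#' @export
normalize_decay <- function(course) {
  stopifnot(all(c("replicate", "time_h", "level") %in% names(course)))
  t0 <- min(course$time_h)
  base <- course$level[course$time_h == t0][
    match(course$replicate, course$replicate[course$time_h == t0])]
  if (any(base <= 0)) stop("nonpositive level at t = 0")
  course$level <- course$level / base
  course
}

#' Summarise a protein-decay time course
#'
#' Per-timepoint mean and SEM of the (replicate-normalised) levels, with, when
#' a second condition is supplied, a per-timepoint two-sided Student's t test
#' between conditions. A log-linear least-squares fit provides an estimated
#' half-life `t_half = ln 2 / k_hat`; the half-life is an extension beyond
#' the per-timepoint comparison and is labelled as such in the output.
#'
#' @param course data frame `replicate`, `time_h`, `level` for condition A.
#' @param course_b optional second condition for per-timepoint t tests.
#' @param normalize normalise each replicate to its t = 0 level first.
#' @return list of class `decay_summary`: `summary` (per-timepoint mean, sem,
#'   n), `half_life_h`, `rate_per_h`, `half_life_note`, and `comparisons`
#'   when `course_b` is given.
#' @export
summarize_decay <- function(course, course_b = NULL, normalize = TRUE) {
  if (normalize) course <- normalize_decay(course)
  if (any(course$level <= 0))
    stop("nonpositive levels; cannot fit the log-linear decay")
  per_t <- function(cs) {
    sp <- split(cs$level, cs$time_h)
    data.frame(time_h = as.numeric(names(sp)),
               mean = vapply(sp, mean, numeric(1)),
               sem = vapply(sp, function(v)
                 if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                 numeric(1)),
               n = vapply(sp, length, numeric(1)),
               row.names = NULL)
  }
  fit <- lm(log(level) ~ time_h, data = course)
  k <- -unname(coef(fit)[2])
  comparisons <- NULL
  if (!is.null(course_b)) {
    if (normalize) course_b <- normalize_decay(course_b)
    tp <- sort(intersect(unique(course$time_h), unique(course_b$time_h)))
    comparisons <- do.call(rbind, lapply(tp, function(t0) {
      a <- course$level[course$time_h == t0]
      b <- course_b$level[course_b$time_h == t0]
      p <- if (sd(c(a, b)) == 0) 1 else t.test(a, b)$p.value
      data.frame(time_h = t0, mean_a = mean(a), mean_b = mean(b), p_value = p)
    }))
  }
  structure(list(summary = per_t(course),
                 rate_per_h = k,
                 half_life_h = if (k > 0) log(2) / k else Inf,
                 half_life_note = paste("half-life from log-linear fit;",
                                        "extension beyond the per-timepoint",
                                        "comparison"),
                 comparisons = comparisons),
            class = "decay_summary")
}

#' @export
print.decay_summary <- function(x, ...) {
  cat("decay summary (levels relative to t = 0):\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("fitted half-life: %.3g h (%s)\n", x$half_life_h,
              x$half_life_note))
  if (!is.null(x$comparisons)) {
    cat("per-timepoint t tests:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
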
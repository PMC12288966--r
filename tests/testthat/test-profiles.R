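render_ellipse_mask <- function(a, b, px = 0.25, angle = 0, pad = 3) {
  ext <- 2 * max(a, b) + 2 * pad
  n <- ceiling(ext / px)
  ctr <- n / 2 * px
  xs <- (seq_len(n) - 0.5) * px - ctr
  X <- outer(xs, rep(1, n)); Y <- outer(rep(1, n), xs)
  u <- X * cos(angle) + Y * sin(angle)
  v <- -X * sin(angle) + Y * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

test_that("the long axis of an ellipse has the right direction and chord", {
  mask <- render_ellipse_mask(8, 4, px = 0.25)
  ax <- long_axis(mask, c(0.25, 0.25))
  expect_lt(abs(abs(ax$direction[1]) - 1), 1e-6)  # major axis along x
  expect_lt(abs(ax$chord_um - 16), 0.25)          # within one pixel
  # circle: degenerate axis resolved along x
  mc <- render_ellipse_mask(5, 5, px = 0.25)
  axc <- long_axis(mc, c(0.25, 0.25))
  expect_equal(axc$direction, c(1, 0))
  expect_lt(abs(axc$chord_um - 10), 0.25)
})

test_that("long axis matches the farthest-pair direction for elongated blobs", {
  for (ang in c(0.3, 1.1, 2.4)) {
    mask <- render_ellipse_mask(9, 3.5, px = 0.25, angle = ang)
    ax <- long_axis(mask, c(0.25, 0.25))
    # brute-force farthest pair over boundary pixels
    pc <- which(mask, arr.ind = TRUE)
    bd <- pc[apply(pc, 1, function(p) {
      nb <- rbind(p + c(1, 0), p - c(1, 0), p + c(0, 1), p - c(0, 1))
      any(nb[, 1] < 1 | nb[, 1] > nrow(mask) |
            nb[, 2] < 1 | nb[, 2] > ncol(mask)) || !all(mask[nb])
    }), , drop = FALSE]
    xy <- bd * 0.25
    dm <- as.matrix(dist(xy))
    far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    fdir <- xy[far[2], ] - xy[far[1], ]
    fdir <- fdir / sqrt(sum(fdir^2))
    cosang <- abs(sum(fdir * ax$direction))
    # the pixelated boundary moves the farthest pair by ~a pixel itself
    expect_gt(cosang, 0.998)  # within ~3.6 degrees
    expect_lt(abs(ax$chord_um - max(dm)), 0.5)
  }
})

test_that("long axis rejects empty or disconnected masks", {
  expect_error(long_axis(matrix(FALSE, 5, 5), c(1, 1)), "empty")
  m <- matrix(FALSE, 10, 10)
  m[1:2, 1:2] <- TRUE
  m[8:9, 8:9] <- TRUE
  expect_error(long_axis(m, c(1, 1)), "components")
})

test_that("profile sampling is exact for constants and linear ramps", {
  const <- voxel_grid(matrix(37, 50, 50), c(0.5, 0.5))
  seg <- list(start = c(3, 12), end = c(20, 12))
  prof <- sample_profile(const, seg, step = 0.1)
  expect_true(all(prof$intensities == 37))
  ramp <- voxel_grid(outer((seq_len(50) - 0.5) * 0.5 * 2, rep(1, 50)),
                     c(0.5, 0.5))
  pr <- sample_profile(ramp, seg, step = 0.1)
  slopes <- diff(pr$intensities) / diff(pr$positions)
  expect_true(all(abs(slopes - 2) < 1e-6))
  expect_error(sample_profile(const, list(start = c(-5, 0), end = c(10, 0))),
               "exits")
})

test_that("rim-enriched nuclei produce edge peaks at the rim", {
  f <- centered_nucleus(radii = c(6, 6, 6), extent = c(26, 26, 18),
                        voxel = 0.25)
  mem <- make_membrane_channel(f$truth,
                               membrane_spec(0.9, rim_width = 1.2), f$grid)
  zc <- round(f$truth$cz_um / 0.25)
  mask <- array(FALSE, dim(f$grid))
  mask[f$idx] <- TRUE
  mask2d <- mask[, , zc]
  ax <- long_axis(mask2d, c(0.25, 0.25))
  prof <- sample_profile(voxel_grid(mem$intensities[, , zc], c(0.25, 0.25), 16L),
                         ax, step = 0.1, mask = mask2d)
  e <- prof$edge_positions
  peak <- prof$positions[which.max(prof$intensities)]
  expect_true(min(abs(peak - e)) < 1.2 + 0.2)
})

test_that("peripheral fraction matches closed forms and an independent sum", {
  # uniform signal, span 10, margin 3 -> 2d/L = 0.6
  pos <- seq(0, 14, by = 0.1)
  uni <- structure(list(positions = pos, intensities = rep(5, length(pos)),
                        edge_positions = c(2, 12), z_plane = 1L, step = 0.1),
                   class = "line_profile")
  pf <- peripheral_fraction(uni, 3)
  expect_lt(abs(pf$value - 0.6), 0.006)
  # all signal within 1 um of the left edge -> 1.0
  conc <- uni
  conc$intensities <- ifelse(pos >= 2 & pos <= 3, 10, 0)
  expect_equal(peripheral_fraction(conc, 3)$value, 1.0, tolerance = 1e-9)
  # discrete profile cross-checked against an independently coded sum
  pos2 <- 0:10
  int2 <- c(5, 5, 5, 5, 1, 1, 1, 5, 5, 5, 5)
  pr2 <- structure(list(positions = as.numeric(pos2), intensities = int2,
                        edge_positions = c(0, 10), z_plane = 1L, step = 1),
                   class = "line_profile")
  got <- peripheral_fraction(pr2, 3)$value
  trap <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  inl <- pos2 <= 3
  inr <- pos2 >= 7
  want <- (trap(pos2[inl], int2[inl]) + trap(pos2[inr], int2[inr])) /
    trap(pos2, int2)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("peripheral fraction is invariant to intensity scaling and flags short spans", {
  pos <- seq(0, 12, by = 0.1)
  y <- dnorm(pos, 6, 2) + 0.1
  p1 <- structure(list(positions = pos, intensities = y,
                       edge_positions = c(1, 11), z_plane = 1L, step = 0.1),
                  class = "line_profile")
  p2 <- p1
  p2$intensities <- y * 273.5
  expect_equal(peripheral_fraction(p1, 3)$value,
               peripheral_fraction(p2, 3)$value, tolerance = 1e-12)
  short <- p1
  short$edge_positions <- c(5, 10)   # span 5 <= 2 * 3
  out <- peripheral_fraction(short, 3)
  expect_true(out$flagged)
  expect_equal(out$value, 1)
  zero <- p1
  zero$intensities[] <- 0
  expect_error(peripheral_fraction(zero, 3), "no signal")
})

test_that("uniform-signal closed form 2d/L holds across spans", {
  for (L in c(7, 10, 16, 25)) {
    pos <- seq(0, L + 4, by = 0.1)
    pr <- structure(list(positions = pos, intensities = rep(2, length(pos)),
                         edge_positions = c(2, 2 + L), z_plane = 1L,
                         step = 0.1),
                    class = "line_profile")
    expect_lt(abs(peripheral_fraction(pr, 3)$value - 6 / L), 0.1 / L + 1e-9)
  }
})

test_that("lane AUC reproduces analytic band areas and normalisation", {
  rect <- c(0, rep(4, 7), 0)   # height 4, width 7 samples -> area 4*7
  expect_equal(lane_auc(rect)$auc, 28)
  ident <- lane_auc(rect, control = rect)
  expect_equal(ident$normalized, 1.0)
  x <- seq(-10, 10, by = 0.05)
  gauss <- 10 * exp(-x^2 / (2 * 2^2))
  got <- lane_auc(gauss, positions = x)$auc
  expect_lt(abs(got / (10 * 2 * sqrt(2 * pi)) - 1), 0.01)
  # linearity under zero background
  expect_equal(lane_auc(3.3 * gauss, positions = x)$auc, 3.3 * got,
               tolerance = 1e-12)
  # background modes
  lifted <- gauss + 5
  expect_equal(lane_auc(lifted, positions = x, background = "min")$auc, got,
               tolerance = 1e-4)
  expect_error(lane_auc(rect, control = rep(0, 9)), "control")
})

test_that("decay summaries fit exact half-lives and compare conditions", {
  exact <- make_decay_course(decay_spec(k = log(2) / 6, noise_cv = 0,
                                        replicates = 3))
  s <- summarize_decay(exact)
  expect_equal(s$half_life_h, 6, tolerance = 1e-9)
  expect_equal(s$summary$mean[s$summary$time_h == 0], 1)
  # identical conditions: all per-timepoint p-values 1
  a <- make_decay_course(decay_spec(k = 0.1, noise_cv = 0.05, seed = 3))
  cmp <- summarize_decay(a, a)
  expect_true(all(abs(cmp$comparisons$p_value - 1) < 1e-9))
  bad <- exact
  bad$level[5] <- -1
  expect_error(summarize_decay(bad, normalize = FALSE), "nonpositive")
})

test_that("half-life recovery from noisy courses is accurate", {
  errs_a <- errs_b <- numeric(100)
  for (s in 1:100) {
    a <- make_decay_course(decay_spec(k = log(2) / 4, noise_cv = 0.05,
                                      replicates = 3, seed = s))
    b <- make_decay_course(decay_spec(k = log(2) / 12, noise_cv = 0.05,
                                      replicates = 3, seed = 1000 + s))
    errs_a[s] <- summarize_decay(a)$half_life_h / 4 - 1
    errs_b[s] <- summarize_decay(b)$half_life_h / 12 - 1
  }
  expect_true(all(abs(errs_a) < 0.15))
  # the slow condition has ~6% sampling SD on k-hat: ask for calibration,
  # not a worst-case bound
  expect_lt(mean(abs(errs_b)), 0.15)
  expect_gte(mean(abs(errs_b) < 0.15), 0.95)
})
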
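test_that("empty field gives pure background and an empty truth table", {
  sp <- field_spec(0, extent = c(20, 20, 10), voxel_size = c(0.5, 0.5, 0.5),
                   noise_sd = 0, background = 12, seed = 1)
  f <- make_nucleus_field(sp)
  expect_equal(nrow(f$truth), 0L)
  expect_true(all(f$grid$intensities == 12))
  expect_equal(dim(f$grid), c(40L, 40L, 20L))
})

test_that("a single sphere carries the exact analytic ground truth", {
  sp <- field_spec(1, extent = c(20, 20, 20), voxel_size = c(0.2, 0.2, 0.2),
                   radii = c(5, 5, 5), radii_gsd = 1, noise_sd = 0, seed = 3)
  f <- make_nucleus_field(sp)
  expect_equal(f$truth$volume_um3, 4 / 3 * pi * 5^3, tolerance = 1e-12)
  expect_equal(f$truth$surface_um2, 4 * pi * 25, tolerance = 1e-6)
  # rendered mass within 5% of analytic volume at fine voxels
  expect_lt(abs(f$truth$rendered_voxels * 0.2^3 / f$truth$volume_um3 - 1), 0.05)
})

test_that("identical spec and seed render bit-identical fields", {
  sp <- field_spec(12, extent = c(60, 60, 20), voxel_size = c(0.5, 0.5, 0.5),
                   seed = 7)
  f1 <- make_nucleus_field(sp)
  f2 <- make_nucleus_field(sp)
  expect_identical(f1$grid$intensities, f2$grid$intensities)
  expect_identical(f1$truth, f2$truth)
  p1 <- make_plane_field(field_spec(30, extent = c(200, 200),
                                    voxel_size = c(0.5, 0.5), radii = c(7, 5),
                                    seed = 3))
  p2 <- make_plane_field(field_spec(30, extent = c(200, 200),
                                    voxel_size = c(0.5, 0.5), radii = c(7, 5),
                                    seed = 3))
  expect_identical(p1$grid$intensities, p2$grid$intensities)
})

test_that("rendered voxel mass tracks the analytic ellipsoid volume", {
  sp <- field_spec(8, extent = c(70, 70, 25), voxel_size = c(0.25, 0.25, 0.25),
                   radii = c(6, 5, 3), radii_gsd = 1.1, noise_sd = 0, seed = 11)
  f <- make_nucleus_field(sp)
  rel <- f$truth$rendered_voxels * 0.25^3 / f$truth$volume_um3 - 1
  expect_true(all(abs(rel) < 0.05))
})

test_that("two-population fields have an exactly m^3 median-volume ratio", {
  sp <- field_spec(40, extent = c(150, 150, 30), voxel_size = c(1, 1, 1),
                   radii = c(6, 5, 3), radii_gsd = 1.15, median_scale = 0.8,
                   seed = 5)
  f <- make_nucleus_field(sp)
  m1 <- median(f$truth$volume_um3[f$truth$population == 1])
  m2 <- median(f$truth$volume_um3[f$truth$population == 2])
  expect_equal(m2 / m1, 0.8^3, tolerance = 1e-12)
})

test_that("overcrowded placement fails with an informative error", {
  sp <- field_spec(40, extent = c(30, 30, 15), voxel_size = c(1, 1, 1),
                   radii = c(5, 5, 5), radii_gsd = 1, min_spacing = 12,
                   max_attempts = 200, seed = 1)
  expect_error(make_nucleus_field(sp), "too crowded")
})

test_that("plane fields carry exact ellipse areas and hex spacing", {
  p <- make_plane_field(field_spec(1, extent = c(50, 50),
                                   voxel_size = c(0.25, 0.25),
                                   radii = c(10, 10), radii_gsd = 1,
                                   noise_sd = 0, seed = 2))
  expect_equal(p$truth$csa_um2, pi * 100, tolerance = 1e-12)
  hx <- make_plane_field(field_spec(60, extent = c(200, 200),
                                    voxel_size = c(1, 1), radii = c(4, 4),
                                    radii_gsd = 1, layout = "hex",
                                    lattice_spacing = 20, noise_sd = 0,
                                    seed = 2))
  ctr <- as.matrix(hx$truth[, c("cx_um", "cy_um")])
  nn <- apply(as.matrix(dist(ctr)), 1, function(r) min(r[r > 0]))
  expect_true(all(abs(nn - 20) < 1e-9))
})

test_that("membrane volume calibration places the requested rim share", {
  sp <- field_spec(1, extent = c(12, 12, 12), voxel_size = c(0.35, 0.35, 0.35),
                   radii = c(3.5, 3.5, 3.5), radii_gsd = 1, noise_sd = 0,
                   seed = 4)
  f <- make_nucleus_field(sp)
  for (rho in c(0.72, 0.52)) {
    mem <- make_membrane_channel(f$truth, membrane_spec(rho, rim_width = 1),
                                 f$grid)
    # brute-force rim share: per-voxel min distance to any background voxel
    mask <- array(FALSE, dim(f$grid))
    mask[nucmorph:::ellipsoid_voxels(dim(f$grid), f$grid$voxel_size,
                                     f$truth[1, ], 3L)] <- TRUE
    fgi <- which(mask)
    bgc <- arrayInd(which(!mask), dim(mask))
    fgc <- arrayInd(fgi, dim(mask))
    mind <- vapply(seq_along(fgi), function(i) {
      d2 <- (bgc[, 1] - fgc[i, 1])^2 + (bgc[, 2] - fgc[i, 2])^2 +
        (bgc[, 3] - fgc[i, 3])^2
      sqrt(min(d2)) * 0.35
    }, numeric(1))
    rim <- fgi[mind <= 1]
    share <- sum(mem$intensities[rim]) / sum(mem$intensities[fgi])
    expect_lt(abs(share - rho), 0.02)
  }
})

test_that("rho = 1 puts all membrane signal in the rim shell", {
  sp <- field_spec(1, extent = c(14, 14, 14), voxel_size = c(0.4, 0.4, 0.4),
                   radii = c(4, 4, 4), radii_gsd = 1, noise_sd = 0, seed = 4)
  f <- make_nucleus_field(sp)
  mem <- make_membrane_channel(f$truth, membrane_spec(1, rim_width = 1.2),
                               f$grid)
  idx <- nucmorph:::ellipsoid_voxels(dim(f$grid), f$grid$voxel_size,
                                     f$truth[1, ], 3L)
  mask <- array(FALSE, dim(f$grid)); mask[idx] <- TRUE
  d <- sqrt(nucmorph:::edt_sq_cpp(as.logical(mask), dim(mask),
                                  f$grid$voxel_size))
  interior <- idx[d[idx] > 1.2 + 1e-9]   # avoid exact-tie membership flips
  expect_true(all(mem$intensities[interior] == 0))
  expect_gt(sum(mem$intensities[idx]), 0)
})

test_that("a uniform membrane channel's rim share equals the voxel ratio", {
  sp <- field_spec(1, extent = c(14, 14, 14), voxel_size = c(0.4, 0.4, 0.4),
                   radii = c(4, 4, 4), radii_gsd = 1, noise_sd = 0, seed = 9)
  f <- make_nucleus_field(sp)
  idx <- nucmorph:::ellipsoid_voxels(dim(f$grid), f$grid$voxel_size,
                                     f$truth[1, ], 3L)
  mask <- array(FALSE, dim(f$grid)); mask[idx] <- TRUE
  d <- sqrt(nucmorph:::edt_sq_cpp(as.logical(mask), dim(mask),
                                  f$grid$voxel_size))
  n_rim <- sum(d[idx] <= 1)
  # requesting exactly the shell volume fraction yields a uniform channel
  mem <- make_membrane_channel(f$truth,
                               membrane_spec(n_rim / length(idx),
                                             rim_width = 1), f$grid)
  share <- sum(mem$intensities[idx[d[idx] <= 1]]) / sum(mem$intensities[idx])
  expect_equal(share, n_rim / length(idx), tolerance = 1e-9)
  expect_lt(diff(range(mem$intensities[idx])) /
              mean(mem$intensities[idx]), 1e-9)
})

test_that("rim width must stay below the smallest semi-axis", {
  sp <- field_spec(1, extent = c(14, 14, 14), voxel_size = c(0.5, 0.5, 0.5),
                   radii = c(4, 4, 2.5), radii_gsd = 1, seed = 1)
  f <- make_nucleus_field(sp)
  expect_error(
    make_membrane_channel(f$truth, membrane_spec(0.5, rim_width = 2.5),
                          f$grid),
    "semi-axis")
})

test_that("decay courses obey the half-life identity and determinism", {
  noiseless <- make_decay_course(decay_spec(k = log(2) / 6, noise_cv = 0,
                                            replicates = 2))
  l0 <- noiseless$level[noiseless$time_h == 0]
  l6 <- noiseless$level[noiseless$time_h == 6]
  expect_equal(l6, l0 / 2, tolerance = 1e-12)
  flat <- make_decay_course(decay_spec(k = 0, noise_cv = 0, replicates = 1))
  expect_true(all(flat$level == flat$level[1]))
  a <- make_decay_course(decay_spec(k = 0.1, noise_cv = 0.1, seed = 42))
  b <- make_decay_course(decay_spec(k = 0.1, noise_cv = 0.1, seed = 42))
  expect_identical(a, b)
})

test_that("field I/O round-trips through TIFF plus sidecar", {
  sp <- field_spec(3, extent = c(40, 40, 14), voxel_size = c(0.5, 0.5, 0.5),
                   radii = c(4, 3.5, 3), seed = 6)
  f <- make_nucleus_field(sp)
  dir <- withr::local_tempdir()
  write_field(f, dir, "fld")
  g <- read_stack(file.path(dir, "fld.tif"))
  expect_equal(g$intensities, f$grid$intensities, ignore_attr = TRUE)
  expect_equal(g$voxel_size, f$grid$voxel_size)
  tr <- read.csv(file.path(dir, "fld_truth.csv"))
  expect_equal(tr$volume_um3, f$truth$volume_um3, tolerance = 1e-8)
})
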
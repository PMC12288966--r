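test_that("volume is exactly voxel count times voxel volume", {
  labels <- array(0L, c(4, 4, 4))
  labels[2, 2, 2] <- 1L
  lm <- label_map(labels, c(0.5, 0.5, 1.0))
  expect_equal(measure_volume(lm), 0.25)
  withr::with_seed(3, {
    labels2 <- array(sample(0:3, 500, replace = TRUE), c(10, 10, 5))
    lm2 <- label_map(labels2, c(0.4, 0.5, 0.6))
    tally <- vapply(1:3, function(k) sum(labels2 == k), numeric(1))
    expect_equal(measure_volume(lm2), tally * 0.12)
  })
})

test_that("a rendered sphere recovers its analytic volume and surface area", {
  sp <- field_spec(1, extent = c(20, 20, 20), voxel_size = c(0.2, 0.2, 0.2),
                   radii = c(5, 5, 5), radii_gsd = 1, noise_sd = 0, seed = 3)
  f <- make_nucleus_field(sp)
  lm <- segment_nuclei(f$grid, smooth_sigma = 0, threshold = 100,
                       exclude_border = FALSE)
  v <- measure_volume(lm)
  expect_lt(abs(v / (4 / 3 * pi * 125) - 1), 0.03)
  s_co <- measure_surface_area(lm, "coarea")
  expect_lt(abs(s_co / (4 * pi * 25) - 1), 0.05)
  # face counting carries the documented staircase factor (~1.5 for spheres)
  s_f <- measure_surface_area(lm, "voxel_faces")
  expect_gt(s_f / (4 * pi * 25), 1.3)
})

test_that("face counting is exact on a cube and matches a brute-force scan", {
  labels <- array(0L, c(10, 10, 10))
  labels[3:6, 3:6, 3:6] <- 1L  # 4^3 cube
  lm <- label_map(labels, c(0.5, 0.5, 0.5))
  expect_equal(as.numeric(measure_surface_area(lm)), 6 * 16 * 0.25)
  withr::with_seed(9, {
    mask <- array(runif(6 * 6 * 6) < 0.4, c(6, 6, 6))
    lm2 <- label_components(mask, c(0.3, 0.5, 0.7))
    got <- measure_surface_area(lm2)
    # O(voxels) neighbour scan oracle
    dims <- dim(mask)
    areas <- numeric(n_objects(lm2))
    fa <- c(0.5 * 0.7, 0.3 * 0.7, 0.3 * 0.5)
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      lb <- lm2$labels[i, j, k]
      if (lb == 0) next
      nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                  c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
      for (r in 1:6) {
        w <- nb[r, ]
        ax <- which(w != c(i, j, k))
        outside <- any(w < 1) || any(w > dims)
        if (outside || lm2$labels[w[1], w[2], w[3]] != lb)
          areas[lb] <- areas[lb] + fa[ax]
      }
    }
    expect_equal(as.numeric(got), areas, tolerance = 1e-12)
  })
})

test_that("CSA is the exact pixel tally and recovers a rendered circle", {
  labels <- matrix(0L, 20, 20)
  labels[5:14, 5:14] <- 1L
  lm <- label_map(labels, c(0.5, 0.5))
  expect_equal(measure_csa(lm), 25)
  p <- make_plane_field(field_spec(1, extent = c(50, 50),
                                   voxel_size = c(0.25, 0.25),
                                   radii = c(10, 10), radii_gsd = 1,
                                   noise_sd = 0, seed = 2))
  lmp <- segment_nuclei(p$grid, smooth_sigma = 0, threshold = 100,
                        exclude_border = FALSE)
  expect_lt(abs(measure_csa(lmp) / (pi * 100) - 1), 0.02)
})

test_that("all measures scale exactly with voxel size", {
  withr::with_seed(21, {
    mask <- array(runif(12 * 12 * 6) < 0.3, c(12, 12, 6))
  })
  s <- 3.2
  lm1 <- label_components(mask, c(0.4, 0.5, 0.6))
  lm2 <- label_components(mask, s * c(0.4, 0.5, 0.6))
  expect_equal(measure_volume(lm2), s^3 * measure_volume(lm1),
               tolerance = 1e-12)
  expect_equal(as.numeric(measure_surface_area(lm2)),
               s^2 * as.numeric(measure_surface_area(lm1)), tolerance = 1e-12)
  t1 <- measure_nuclei(lm1); t2 <- measure_nuclei(lm2)
  expect_equal(t2$equivalent_diameter_um, s * t1$equivalent_diameter_um,
               tolerance = 1e-12)
})

test_that("mid-plane CSA and volume are consistent for a sphere", {
  sp <- field_spec(1, extent = c(16, 16, 16), voxel_size = c(0.2, 0.2, 0.2),
                   radii = c(4, 4, 4), radii_gsd = 1, noise_sd = 0, seed = 5)
  f <- make_nucleus_field(sp)
  lm <- segment_nuclei(f$grid, smooth_sigma = 0, threshold = 100,
                       exclude_border = FALSE)
  v <- measure_volume(lm)
  zc <- round(f$truth$cz_um / 0.2)
  plane <- label_map(lm$labels[, , zc], c(0.2, 0.2))
  csa <- measure_csa(plane)
  expect_lt(abs(csa / (pi * (3 * v / (4 * pi))^(2 / 3)) - 1), 0.05)
})

test_that("per-label mean intensities match a brute-force tally", {
  labels <- array(0L, c(8, 8, 4))
  labels[1:3, 1:3, 1:2] <- 1L
  labels[5:7, 5:7, 3:4] <- 2L
  lm <- label_map(labels, c(1, 1, 1))
  ch <- array(0, dim(labels))
  ch[labels == 1L] <- 100
  ch[labels == 2L] <- 200
  g <- voxel_grid(ch, c(1, 1, 1))
  expect_equal(measure_intensity(lm, g), c(100, 200))
  withr::with_seed(2, {
    chr <- array(runif(length(labels), 0, 255), dim(labels))
  })
  gr <- voxel_grid(chr, c(1, 1, 1))
  expect_equal(measure_intensity(lm, gr),
               c(mean(chr[labels == 1L]), mean(chr[labels == 2L])))
  uni <- voxel_grid(array(7, dim(labels)), c(1, 1, 1))
  expect_equal(measure_intensity(lm, uni), c(7, 7))
  bad <- voxel_grid(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_error(measure_intensity(lm, bad), "shape")
})

test_that("cytoplasm-by-subtraction handles clean and noisy inputs", {
  cv <- cytoplasm_volume(1000, 400)
  expect_equal(cv$cytoplasm_volume, 600)
  expect_equal(cytoplasm_volume(500, 500)$cytoplasm_volume, 0)
  expect_warning(cl <- cytoplasm_volume(100, 110), "clamped")
  expect_equal(cl$cytoplasm_volume, 0)
  expect_true(cl$clamped)
  expect_error(cytoplasm_volume(100, 160), "1.5x")
  # synthetic cell: outer ellipsoid minus inner ellipsoid shell
  sp <- field_spec(1, extent = c(24, 24, 24), voxel_size = c(0.25, 0.25, 0.25),
                   radii = c(8, 8, 6), radii_gsd = 1, noise_sd = 0, seed = 3)
  cell <- make_nucleus_field(sp)
  tr <- cell$truth
  tr$a_um <- 5; tr$b_um <- 5; tr$c_um <- 4
  arrn <- array(0, dim(cell$grid))
  arrn[nucmorph:::ellipsoid_voxels(dim(cell$grid), cell$grid$voxel_size,
                                   tr[1, ], 3L)] <- 200
  lmc <- segment_nuclei(cell$grid, smooth_sigma = 0, threshold = 100,
                        exclude_border = FALSE)
  lmn <- segment_nuclei(voxel_grid(arrn, cell$grid$voxel_size),
                        smooth_sigma = 0, threshold = 100,
                        exclude_border = FALSE)
  got <- cytoplasm_volume(measure_volume(lmc), measure_volume(lmn))
  shell <- 4 / 3 * pi * (8 * 8 * 6 - 5 * 5 * 4)
  expect_lt(abs(got$cytoplasm_volume / shell - 1), 0.05)
})

test_that("ground-truth recovery holds across a whole field", {
  sp <- field_spec(6, extent = c(60, 60, 22), voxel_size = c(0.25, 0.25, 0.25),
                   radii = c(5, 4, 3), radii_gsd = 1.08, noise_sd = 4,
                   seed = 13)
  f <- make_nucleus_field(sp)
  lm <- segment_nuclei(f$grid, smooth_sigma = 0.4, exclude_border = FALSE)
  expect_equal(n_objects(lm), 6L)
  tab <- measure_nuclei(lm, surface_method = "coarea")
  # match measured to truth by centroid
  ord <- vapply(seq_len(nrow(tab)), function(i)
    which.min((f$truth$cx_um - tab$centroid_x_um[i])^2 +
                (f$truth$cy_um - tab$centroid_y_um[i])^2 +
                (f$truth$cz_um - tab$centroid_z_um[i])^2), integer(1))
  rel_v <- tab$volume_um3 / f$truth$volume_um3[ord] - 1
  rel_s <- tab$surface_area_um2 / f$truth$surface_um2[ord] - 1
  expect_true(mean(abs(rel_v) < 0.05) >= 0.95)
  expect_true(mean(abs(rel_s) < 0.07) >= 0.95)
})
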
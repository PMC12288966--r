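#' Specification of a synthetic nuclear field
#'
#' Describes a field of ellipsoidal, DAPI-like nuclei rendered into a
#' calibrated intensity volume (or plane), together with exact analytic ground
#' truth. Per-axis semi-axes are drawn lognormally around `radii` with
#' geometric SD `radii_gsd`. When `median_scale != 1` the field carries two
#' equally sized populations; population 2 reuses population 1's draws scaled
#' by `median_scale`, so the ground-truth median volume ratio is exactly
#' `median_scale^3` (a variance-matched paired design; `n_nuclei` should be
#' even in that case).
#'
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param extent physical field size in um, `c(x, y, z)` (or `c(x, y)` via
#'   [make_plane_field()]).
#' @param voxel_size um per voxel, same length as `extent`.
#' @param radii median semi-axes `c(a, b, c)` in um (for planes only the first
#'   two are used).
#' @param radii_gsd geometric SD of the lognormal semi-axis distribution
#'   (1 = monodisperse).
#' @param median_scale multiplier applied to population 2's semi-axes.
#' @param min_spacing minimum centre-to-centre distance in um; default
#'   2.2 x max(radii) prevents overlap of typical neighbours.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param background constant background level (intensity units).
#' @param fg_level foreground (nuclear) intensity added above background.
#' @param bit_depth 8 or 16; rendered intensities are clipped to this range.
#' @param layout `"random"` (Poisson-disc style rejection sampling) or
#'   `"hex"` (hexagonal lattice with spacing `lattice_spacing`, planes only).
#' @param lattice_spacing lattice constant in um for `layout = "hex"`.
#' @param rotate if `TRUE`, each nucleus is rotated in the xy-plane by a
#'   uniform random angle; off by default so analytic axes stay axis-aligned.
#' @param max_attempts placement attempts per nucleus before giving up.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return a list of class `field_spec`.
#' @seealso [make_nucleus_field()], [make_plane_field()]
#' @export
field_spec <- function(n_nuclei,
                       extent = c(100, 100, 30),
                       voxel_size = c(0.25, 0.25, 0.25),
                       radii = c(6, 5, 3),
                       radii_gsd = 1.08,
                       median_scale = 1,
                       min_spacing = NULL,
                       noise_sd = 5,
                       background = 10,
                       fg_level = 180,
                       bit_depth = 8L,
                       layout = c("random", "hex"),
                       lattice_spacing = NULL,
                       rotate = FALSE,
                       max_attempts = 10000L,
                       seed = 1L) {
  layout <- match.arg(layout)
  if (n_nuclei < 0) stop("`n_nuclei` must be >= 0")
  if (any(extent <= 0) || any(voxel_size <= 0))
    stop("extents and voxel sizes must be positive")
  if (median_scale <= 0) stop("`median_scale` must be positive")
  if (radii_gsd < 1) stop("`radii_gsd` must be >= 1")
  if (is.null(min_spacing)) min_spacing <- 2.2 * max(radii)
  if (min_spacing <= 0) stop("`min_spacing` must be positive")
  structure(list(
    n_nuclei = as.integer(n_nuclei), extent = extent,
    voxel_size = voxel_size, radii = radii, radii_gsd = radii_gsd,
    median_scale = median_scale, min_spacing = min_spacing,
    noise_sd = noise_sd, background = background, fg_level = fg_level,
    bit_depth = as.integer(bit_depth), layout = layout,
    lattice_spacing = lattice_spacing, rotate = rotate,
    max_attempts = as.integer(max_attempts), seed = as.integer(seed)),
    class = "field_spec")
}

# Knud Thomsen's approximation to the ellipsoid surface area (relative error
# below ~1.1% for any axis ratio).
ellipsoid_surface_area <- function(a, b, c, p = 1.6075) {
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

# Draw semi-axes and population labels; population 2 = scaled copy of
# population 1's draws so the median-volume ratio is exact.
draw_radii <- function(spec, ndim) {
  n <- spec$n_nuclei
  r0 <- spec$radii[seq_len(ndim)]
  sdlog <- log(spec$radii_gsd)
  two_pop <- spec$median_scale != 1
  n1 <- if (two_pop) ceiling(n / 2) else n
  base <- matrix(exp(rnorm(n1 * ndim, 0, sdlog)), n1, ndim)
  base <- sweep(base, 2, r0, `*`)
  if (!two_pop)
    return(list(radii = base, population = rep(1L, n)))
  n2 <- n - n1
  radii <- rbind(base, base[seq_len(n2), , drop = FALSE] * spec$median_scale)
  list(radii = radii, population = rep(c(1L, 2L), c(n1, n2)))
}

# Rejection-sampled centres keeping every nucleus fully interior and all
# centre pairs >= min_spacing apart.
place_centers <- function(spec, radii, ndim) {
  n <- nrow(radii)
  ext <- spec$extent[seq_len(ndim)]
  centers <- matrix(NA_real_, n, ndim)
  for (i in seq_len(n)) {
    margin <- max(radii[i, ])
    lo <- rep(margin, ndim)
    hi <- ext - margin
    if (any(hi <= lo))
      stop("field too crowded: nucleus ", i, " (max semi-axis ", signif(margin, 3),
           " um) does not fit in extent ", paste(ext, collapse = " x "), " um")
    ok <- FALSE
    for (att in seq_len(spec$max_attempts)) {
      p <- lo + runif(ndim) * (hi - lo)
      if (i == 1L ||
          all(sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - p)^2)) >=
              spec$min_spacing)) {
        centers[i, ] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("field too crowded: failed to place nucleus ", i, " of ", n,
           " after ", spec$max_attempts, " attempts (extent ",
           paste(ext, collapse = " x "), " um, min_spacing ",
           spec$min_spacing, " um, n_nuclei ", n, ")")
  }
  centers
}

hex_centers <- function(spec, margin) {
  s <- spec$lattice_spacing
  if (is.null(s) || s <= 0)
    stop("`lattice_spacing` must be set for layout = \"hex\"")
  ext <- spec$extent[1:2]
  xs <- seq(margin, ext[1] - margin, by = s)
  ys <- seq(margin, ext[2] - margin, by = s * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) s / 2 else 0
    x <- xs + off
    x <- x[x <= ext[1] - margin]
    cbind(x, ys[r])
  }))
  pts
}

# Paint ellipsoids (value fg_level) into a zero array; returns the array and
# per-nucleus rendered voxel counts. Voxel i spans [(i-1)h, ih), centre at
# (i-0.5)h. `angle` rotates the (a, b) axes in the xy-plane.
render_ellipsoids <- function(dims, voxel_size, truth, value) {
  ndim <- length(dims)
  arr <- array(0, dims)
  counts <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    idx <- ellipsoid_voxels(dims, voxel_size, truth[i, ], ndim)
    counts[i] <- length(idx)
    arr[idx] <- value
  }
  list(arr = arr, counts = counts)
}

# Linear indices of voxels whose centres fall inside one ellipsoid.
ellipsoid_voxels <- function(dims, voxel_size, row, ndim) {
  ctr <- as.numeric(row[c("cx_um", "cy_um", "cz_um")[seq_len(ndim)]])
  ax <- as.numeric(row[c("a_um", "b_um", "c_um")[seq_len(ndim)]])
  ang <- if ("angle_rad" %in% names(row)) as.numeric(row[["angle_rad"]]) else 0
  rng <- lapply(seq_len(ndim), function(j) {
    pad <- max(ax[1:min(2, ndim)])          # xy rotation can mix a and b
    if (j == 3) pad <- ax[3]
    lo <- max(1L, floor((ctr[j] - pad) / voxel_size[j]))
    hi <- min(dims[j], ceiling((ctr[j] + pad) / voxel_size[j] + 1))
    lo:hi
  })
  cc <- lapply(seq_len(ndim), function(j) (rng[[j]] - 0.5) * voxel_size[j] - ctr[j])
  if (ndim == 2L) {
    X <- outer(cc[[1]], rep(1, length(cc[[2]])))
    Y <- outer(rep(1, length(cc[[1]])), cc[[2]])
    u <- X * cos(ang) + Y * sin(ang)
    v <- -X * sin(ang) + Y * cos(ang)
    inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
    ij <- which(inside, arr.ind = TRUE)
    if (!nrow(ij)) return(integer(0))
    (rng[[1]][ij[, 1]]) + (rng[[2]][ij[, 2]] - 1L) * dims[1]
  } else {
    nx <- length(cc[[1]]); ny <- length(cc[[2]]); nz <- length(cc[[3]])
    X <- array(rep(cc[[1]], times = ny * nz), c(nx, ny, nz))
    Y <- array(rep(rep(cc[[2]], each = nx), times = nz), c(nx, ny, nz))
    Z <- array(rep(cc[[3]], each = nx * ny), c(nx, ny, nz))
    u <- X * cos(ang) + Y * sin(ang)
    v <- -X * sin(ang) + Y * cos(ang)
    inside <- (u / ax[1])^2 + (v / ax[2])^2 + (Z / ax[3])^2 <= 1
    ijk <- which(inside, arr.ind = TRUE)
    if (!nrow(ijk)) return(integer(0))
    (rng[[1]][ijk[, 1]]) +
      (rng[[2]][ijk[, 2]] - 1L) * dims[1] +
      (rng[[3]][ijk[, 3]] - 1L) * dims[1] * dims[2]
  }
}

build_truth <- function(centers, radii, population, angles, ndim) {
  if (ndim == 2L) {
    data.frame(
      id = seq_len(nrow(centers)),
      population = population,
      cx_um = centers[, 1], cy_um = centers[, 2],
      a_um = radii[, 1], b_um = radii[, 2],
      angle_rad = angles,
      csa_um2 = pi * radii[, 1] * radii[, 2])
  } else {
    data.frame(
      id = seq_len(nrow(centers)),
      population = population,
      cx_um = centers[, 1], cy_um = centers[, 2], cz_um = centers[, 3],
      a_um = radii[, 1], b_um = radii[, 2], c_um = radii[, 3],
      angle_rad = angles,
      volume_um3 = 4 / 3 * pi * radii[, 1] * radii[, 2] * radii[, 3],
      surface_um2 = ellipsoid_surface_area(radii[, 1], radii[, 2], radii[, 3]))
  }
}

make_field <- function(spec, ndim) {
  dims <- as.integer(round(spec$extent[seq_len(ndim)] /
                             spec$voxel_size[seq_len(ndim)]))
  withr::with_seed(spec$seed, {
    if (spec$n_nuclei == 0L) {
      truth <- build_truth(matrix(numeric(0), 0, ndim),
                           matrix(numeric(0), 0, ndim),
                           integer(0), numeric(0), ndim)
      fg <- list(arr = array(0, dims), counts = numeric(0))
    } else {
      dr <- draw_radii(spec, ndim)
      if (spec$layout == "hex" && ndim == 2L) {
        centers <- hex_centers(spec, max(dr$radii))
        keep <- seq_len(min(nrow(centers), spec$n_nuclei))
        centers <- centers[keep, , drop = FALSE]
        dr$radii <- dr$radii[seq_along(keep), , drop = FALSE]
        dr$population <- dr$population[seq_along(keep)]
      } else {
        centers <- place_centers(spec, dr$radii, ndim)
      }
      angles <- if (spec$rotate) runif(nrow(centers), 0, pi) else
        rep(0, nrow(centers))
      truth <- build_truth(centers, dr$radii, dr$population, angles, ndim)
      fg <- render_ellipsoids(dims, spec$voxel_size[seq_len(ndim)], truth,
                              spec$fg_level)
    }
    arr <- fg$arr + spec$background
    if (spec$noise_sd > 0)
      arr <- arr + rnorm(length(arr), 0, spec$noise_sd)
    arr <- round(pmin(pmax(arr, 0), 2^spec$bit_depth - 1))
    dim(arr) <- dims
    truth$rendered_voxels <- fg$counts
    list(grid = voxel_grid(arr, spec$voxel_size[seq_len(ndim)],
                           spec$bit_depth),
         truth = truth)
  })
}

#' Render a 3D field of ellipsoidal nuclei with exact ground truth
#'
#' Emulates a DAPI-stained confocal stack: bright axis-aligned (optionally
#' xy-rotated) ellipsoids over a noisy constant background, clipped to the
#' bit depth. The companion table carries, per nucleus, the exact centre,
#' semi-axes, analytic volume `4/3*pi*a*b*c` and Knud-Thomsen surface area,
#' the population label, and the rendered foreground voxel count.
#'
#' @param spec a [field_spec()] (3-component `extent`/`voxel_size`).
#' @return list with elements `grid` (a [voxel_grid]) and `truth`
#'   (a data frame, one row per placed nucleus).
#' @examples
#' f <- make_nucleus_field(field_spec(3, extent = c(60, 60, 24),
#'                                    voxel_size = c(0.5, 0.5, 0.5), seed = 2))
#' f$truth$volume_um3
#' @export
make_nucleus_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  make_field(spec, 3L)
}

#' Render a 2D plane of elliptical nuclei with exact ground truth
#'
#' 2D analogue of [make_nucleus_field()]; stands in for an H&E/Feulgen
#' "optical density" plane. Ground truth carries the analytic ellipse area
#' `pi*a*b`. `layout = "hex"` places nuclei on a hexagonal lattice with
#' spacing `lattice_spacing` (every interior nearest-centre distance equals
#' the spacing), which is convenient for spatial-statistics oracles.
#'
#' @param spec a [field_spec()]; only the first two components of
#'   `extent`/`voxel_size`/`radii` are used.
#' @return list with elements `grid` and `truth`.
#' @export
make_plane_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  make_field(spec, 2L)
}

#' Specification of a nuclear-membrane channel
#'
#' Defines how a membrane-protein channel (an Emerin analogue) is painted
#' into the nuclei of an existing field: a fraction `rim_fraction` of each
#' nucleus's total signal is placed in a rim shell within `rim_width` um of
#' the nuclear surface (Euclidean distance on the rendered voxel mask), the
#' remainder uniformly in the interior.
#'
#' Two calibration modes are provided because a 1D line scan through a 3D
#' shell does not weight rim and interior the way voxel sums do:
#' * `"volume"` (default): `rim_fraction` is the volumetric share — the voxel
#'   sum over the rim shell is exactly `rim_fraction` of the nucleus total.
#' * `"linescan"`: rim intensity is solved per nucleus so that the *expected
#'   long-axis mid-plane line-scan peripheral fraction* (margin
#'   `margin_um`) equals `rim_fraction`; this is the quantity the line-scan
#'   assay reports, so use this mode when simulating peripheral-enrichment
#'   percentages.
#'
#' @param rim_fraction target fraction in \[0, 1\].
#' @param rim_width rim shell thickness in um; must be smaller than the
#'   smallest nuclear semi-axis.
#' @param interior_level interior intensity (arbitrary units) used as the
#'   base level; ignored (solved) where the calibration fixes it.
#' @param calibration `"volume"` or `"linescan"`.
#' @param margin_um line-scan margin used by the `"linescan"` calibration.
#' @param seed integer seed (reserved; rendering is deterministic).
#' @return a list of class `membrane_spec`.
#' @export
membrane_spec <- function(rim_fraction, rim_width = 1, interior_level = 50,
                          calibration = c("volume", "linescan"),
                          margin_um = 3, seed = 1L) {
  calibration <- match.arg(calibration)
  if (rim_fraction < 0 || rim_fraction > 1)
    stop("`rim_fraction` must lie in [0, 1]")
  if (rim_width <= 0) stop("`rim_width` must be positive")
  structure(list(rim_fraction = rim_fraction, rim_width = rim_width,
                 interior_level = interior_level, calibration = calibration,
                 margin_um = margin_um, seed = as.integer(seed)),
            class = "membrane_spec")
}

#' Render the membrane channel for an existing nuclear field
#'
#' @param truth ground-truth table from [make_nucleus_field()].
#' @param mspec a [membrane_spec()].
#' @param grid the field's [voxel_grid] (supplies geometry; intensities are
#'   not read).
#' @return a [voxel_grid] with the membrane channel (16-bit scale, float
#'   intensities).
#' @export
make_membrane_channel <- function(truth, mspec, grid) {
  stopifnot(inherits(mspec, "membrane_spec"), inherits(grid, "voxel_grid"))
  dims <- dim(grid)
  vs <- grid$voxel_size
  ndim <- length(dims)
  if (nrow(truth) > 0) {
    min_semi <- min(as.matrix(truth[, c("a_um", "b_um", "c_um")[seq_len(ndim)]]))
    if (mspec$rim_width >= min_semi)
      stop("rim_width (", mspec$rim_width,
           " um) must be smaller than the smallest nuclear semi-axis (",
           signif(min_semi, 3), " um)")
  }
  arr <- array(0, dims)
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    idx <- ellipsoid_voxels(dims, vs, row, ndim)
    if (!length(idx)) next
    sub <- crop_mask(idx, dims)
    dist <- sqrt(edt_sq_cpp(sub$mask, sub$dims, vs))
    rim_local <- sub$mask & dist <= mspec$rim_width
    rim <- idx[rim_local[sub$mask]]
    interior <- setdiff(idx, rim)
    n_rim <- length(rim); n_int <- length(interior)
    rho <- mspec$rim_fraction
    if (mspec$calibration == "volume") {
      S <- 100 * length(idx)  # mean intensity 100 per nucleus
      i_rim <- if (n_rim) rho * S / n_rim else 0
      i_int <- if (n_int) (1 - rho) * S / n_int else 0
    } else {
      lev <- linescan_levels(row, sub, dist, vs, mspec, ndim)
      i_rim <- lev$i_rim
      i_int <- lev$i_int
    }
    arr[rim] <- i_rim
    arr[interior] <- i_int
  }
  voxel_grid(arr, vs, 16L)
}

# Bounding-box crop of a voxel index set, padded with one background voxel so
# the distance transform sees the surface on all sides.
crop_mask <- function(idx, dims) {
  nd <- length(dims)
  coords <- arrayInd(idx, dims)
  lo <- pmax(apply(coords, 2, min) - 1L, 1L)
  hi <- pmin(apply(coords, 2, max) + 1L, dims)
  sub_dims <- hi - lo + 1L
  mask <- array(FALSE, sub_dims)
  loc <- sweep(coords, 2, lo - 1L, `-`)
  lin <- loc[, 1]
  mult <- 1
  for (j in seq_len(nd - 1)) {
    mult <- mult * sub_dims[j]
    lin <- lin + (loc[, j + 1] - 1L) * mult
  }
  mask[lin] <- TRUE
  list(mask = mask, dims = sub_dims, lo = lo)
}

# Solve rim/interior intensity levels so the expected long-axis line-scan
# peripheral fraction equals rho. Membership tallies are taken along the
# nucleus's in-plane major axis at its central z, on the rendered masks.
linescan_levels <- function(row, sub, dist, vs, mspec, ndim) {
  rho <- mspec$rim_fraction
  d <- mspec$margin_um
  w <- mspec$rim_width
  ax <- as.numeric(row[c("a_um", "b_um")])
  ang <- as.numeric(row[["angle_rad"]])
  if (ax[2] > ax[1]) { ax <- rev(ax); ang <- ang + pi / 2 }
  dirv <- c(cos(ang), sin(ang), 0)[seq_len(ndim)]
  ctr <- as.numeric(row[c("cx_um", "cy_um", "cz_um")[seq_len(ndim)]])
  step <- min(vs[1:2]) / 4
  ts <- seq(-ax[1] - 1, ax[1] + 1, by = step)
  rim3 <- array(sub$mask & dist <= w, sub$dims)
  inside <- rim_flag <- logical(length(ts))
  for (k in seq_along(ts)) {
    p <- ctr + ts[k] * dirv
    ix <- pmin(pmax(ceiling(p / vs[seq_len(ndim)]), 1L), sub$dims + sub$lo - 1L)
    loc <- ix - (sub$lo - 1L)
    if (any(loc < 1L) || any(loc > sub$dims)) next
    loc_l <- as.list(loc)
    inside[k] <- do.call(`[`, c(list(array(sub$mask, sub$dims)), loc_l))
    rim_flag[k] <- do.call(`[`, c(list(rim3), loc_l))
  }
  ii <- which(inside)
  if (!length(ii)) stop("nucleus ", row[["id"]], " has no in-plane axis samples")
  t_in <- ts[ii]
  p_l <- min(t_in); p_r <- max(t_in)
  margin <- t_in <= p_l + d | t_in >= p_r - d
  rim_in <- rim_flag[ii]
  t_r <- sum(rim_in); t_i <- sum(!rim_in)
  m_r <- sum(margin & rim_in); m_i <- sum(margin & !rim_in)
  denom <- m_r - rho * t_r
  numer <- rho * t_i - m_i
  lo_f <- if (t_i) m_i / t_i else 0
  hi_f <- if (t_r) m_r / t_r else 1
  if (denom <= 0 || numer < 0)
    stop("line-scan calibration infeasible for nucleus ", row[["id"]],
         ": requested fraction ", rho, " outside attainable range [",
         signif(lo_f, 3), ", ", signif(hi_f, 3),
         "] for this geometry (rim_width ", w, " um, margin ", d, " um)")
  i_int <- mspec$interior_level
  if (i_int <= 0) i_int <- 50
  list(i_rim = i_int * numer / denom, i_int = i_int)
}

#' Specification of an exponential protein-decay time course
#'
#' Emulates a cycloheximide-chase experiment: protein level
#' `initial_level * exp(-k t)` sampled at `timepoints` hours with
#' multiplicative lognormal noise of coefficient of variation `noise_cv`
#' across `replicates` independent replicates.
#'
#' @param k decay rate constant (1/hour), `k >= 0`.
#' @param initial_level level at t = 0 (arbitrary units).
#' @param timepoints sampling times in hours, nonnegative and strictly
#'   increasing; default `c(0, 6, 12)`.
#' @param noise_cv coefficient of variation of the lognormal noise (0 =
#'   noiseless).
#' @param replicates number of replicates (>= 1).
#' @param seed integer seed.
#' @return a list of class `decay_spec`.
#' @export
decay_spec <- function(k, initial_level = 1, timepoints = c(0, 6, 12),
                       noise_cv = 0, replicates = 3L, seed = 1L) {
  if (k < 0) stop("`k` must be >= 0")
  if (any(timepoints < 0) || any(diff(timepoints) <= 0))
    stop("`timepoints` must be nonnegative and strictly increasing")
  if (replicates < 1) stop("`replicates` must be >= 1")
  if (noise_cv < 0) stop("`noise_cv` must be >= 0")
  structure(list(k = k, initial_level = initial_level,
                 timepoints = timepoints, noise_cv = noise_cv,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "decay_spec")
}

#' Simulate a replicate-by-timepoint decay course
#'
#' @param dspec a [decay_spec()].
#' @return data frame with columns `replicate`, `time_h`, `level`; one row per
#'   replicate x timepoint. Noise is mean-one lognormal so expected levels
#'   follow the exact exponential.
#' @examples
#' make_decay_course(decay_spec(k = log(2) / 6, noise_cv = 0, replicates = 1))
#' @export
make_decay_course <- function(dspec) {
  stopifnot(inherits(dspec, "decay_spec"))
  withr::with_seed(dspec$seed, {
    grid <- expand.grid(replicate = seq_len(dspec$replicates),
                        time_h = dspec$timepoints)
    level <- dspec$initial_level * exp(-dspec$k * grid$time_h)
    if (dspec$noise_cv > 0) {
      sdlog <- sqrt(log(1 + dspec$noise_cv^2))
      level <- level * rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    data.frame(replicate = grid$replicate, time_h = grid$time_h, level = level)
  })
}

#' Write a synthetic field (image + sidecar + ground truth) to a directory
#'
#' @param field list from [make_nucleus_field()] / [make_plane_field()].
#' @param dir output directory (created if needed).
#' @param name file stem, default `"field"`.
#' @return the directory, invisibly.
#' @export
write_field <- function(field, dir, name = "field") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(field$grid, file.path(dir, paste0(name, ".tif")))
  write.csv(field$truth, file.path(dir, paste0(name, "_truth.csv")),
            row.names = FALSE)
  invisible(dir)
}
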
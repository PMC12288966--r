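#' Configuration for an end-to-end analysis run
#'
#' Bundles every knob of a pipeline run in one serialisable object. Each
#' condition is either a simulation spec ([field_spec()], optionally paired
#' with a [membrane_spec()]) or a list of image paths with calibration.
#' All defaults are resolved here so the effective configuration written next
#' to the results fully reproduces the run. Per-condition simulation seeds
#' are derived deterministically from `seed` (seed + 7919 * condition index).
#'
#' @param conditions named list; each element is a [field_spec()], or a list
#'   with elements `spec` (a `field_spec`) and optionally `membrane`
#'   (a [membrane_spec()]), or a list with `paths` (TIFF files) and
#'   `voxel_size`.
#' @param segmentation list: `smooth_sigma` (um), `threshold` (`"otsu"` or a
#'   value), `connectivity`, `min_size`, `exclude_border`,
#'   `max_solidity_deficit`.
#' @param roi list: `box_size` (um), `n_boxes`, `exclusion_mask`,
#'   `mask_pixel_size` (for the CSA pipeline).
#' @param linescan list: `margin_um`, `step` (for the line-scan pipeline).
#' @param policy a [test_policy()].
#' @param surface_method surface-area estimator for 3D runs.
#' @param out_dir optional output directory; when set, result tables, the
#'   effective config and a plain-text report are written there.
#' @param seed integer master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(conditions,
                       segmentation = list(),
                       roi = list(),
                       linescan = list(),
                       policy = test_policy(),
                       surface_method = "voxel_faces",
                       out_dir = NULL,
                       seed = 1L) {
  seg <- utils::modifyList(
    list(smooth_sigma = 0.5, threshold = "otsu", connectivity = "face",
         min_size = 50L, exclude_border = TRUE, max_solidity_deficit = NULL),
    segmentation)
  roi <- utils::modifyList(
    list(box_size = 1500, n_boxes = 8L, exclusion_mask = NULL,
         mask_pixel_size = NULL), roi)
  ls <- utils::modifyList(list(margin_um = 3, step = 0.1), linescan)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("`conditions` must be a fully named list")
  structure(list(conditions = conditions, segmentation = seg, roi = roi,
                 linescan = ls, policy = policy,
                 surface_method = surface_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

condition_field <- function(cond, config, index, maker) {
  if (inherits(cond, "field_spec")) cond <- list(spec = cond)
  if (!is.null(cond$spec)) {
    spec <- cond$spec
    spec$seed <- config$seed + 7919L * index
    field <- maker(spec)
    field$membrane <- if (!is.null(cond$membrane))
      make_membrane_channel(field$truth, cond$membrane, field$grid)
    field
  } else if (!is.null(cond$paths)) {
    grids <- lapply(cond$paths, read_stack, voxel_size = cond$voxel_size)
    list(grid = grids[[1]], truth = NULL, membrane = NULL)
  } else stop("condition must supply a simulation `spec` or image `paths`")
}

segment_with <- function(grid, config) {
  s <- config$segmentation
  segment_nuclei(grid, smooth_sigma = s$smooth_sigma,
                 threshold = s$threshold, connectivity = s$connectivity,
                 min_size = s$min_size, exclude_border = s$exclude_border,
                 max_solidity_deficit = s$max_solidity_deficit)
}

compare_conditions <- function(tab, column, policy) {
  conds <- unique(tab$condition)
  if (length(conds) < 2L || nrow(tab) == 0) return(NULL)
  groups <- lapply(conds, function(cn) tab[[column]][tab$condition == cn])
  names(groups) <- conds
  if (any(!lengths(groups))) return(NULL)
  if (length(groups) == 2L)
    compare_two(groups[[1]], groups[[2]], policy, labels = conds)
  else compare_many(groups, policy)
}

new_bundle <- function(config, tables, comparison, stage_log) {
  structure(list(tables = tables, comparison = comparison,
                 stage_log = stage_log,
                 provenance = list(seed = config$seed,
                                   segmentation = config$segmentation,
                                   surface_method = config$surface_method,
                                   package_version =
                                     as.character(packageVersion("nucmorph")))),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d rows\n", nm, nrow(x$tables[[nm]])))
  for (line in x$stage_log) cat(" ", line, "\n")
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Nuclear-volume pipeline: simulate/read, segment, measure, compare
#'
#' For each condition: render (or read) the stack, smooth, threshold, label,
#' filter, and measure every surviving nucleus; then compare the per-nucleus
#' volume distributions across conditions with the policy's normality-gated
#' test. Object counts into and out of every filter are logged per condition.
#'
#' @param config a [run_config()] with 3D conditions.
#' @return a `results_bundle` with tables `nuclei` (per-nucleus morphometry,
#'   with `condition` and provenance of the segmentation), the volume
#'   `comparison`, and a stage log.
#' @export
run_volume_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  stage_log <- character(0)
  for (i in seq_along(config$conditions)) {
    cname <- names(config$conditions)[i]
    field <- condition_field(config$conditions[[i]], config, i,
                             make_nucleus_field)
    lm <- segment_with(field$grid, config)
    rem <- lm$provenance$removed
    stage_log <- c(stage_log, sprintf(
      "%s: %d objects after filtering (removed: %d small, %d border, %d aggregated); threshold %s = %s",
      cname, n_objects(lm), rem$small, rem$border, rem$aggregated,
      lm$provenance$threshold_mode, format(lm$provenance$threshold)))
    if (n_objects(lm) == 0L) {
      warning("condition ", cname, ": no nuclei survived filtering")
      next
    }
    tab <- measure_nuclei(lm, surface_method = config$surface_method)
    tab <- cbind(condition = cname, tab)
    rows[[cname]] <- tab
  }
  nuclei <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(condition = character(0), id = integer(0),
                    volume_um3 = numeric(0))
  comparison <- compare_conditions(nuclei, "volume_um3", config$policy)
  bundle <- new_bundle(config, list(nuclei = nuclei), comparison, stage_log)
  maybe_write(bundle, config)
}

#' Nuclear-CSA pipeline over tiled ROIs, with crowding indices
#'
#' For each condition: render (or read) the plane, tile random ROI boxes over
#' it, and within every box segment nuclei, measure cross-sectional areas,
#' and compute the Delaunay crowding table. Conditions are compared on CSA
#' and on the crowding index.
#'
#' @param config a [run_config()] with 2D conditions.
#' @return a `results_bundle` with tables `nuclei` (per-nucleus, with
#'   `condition` and `box`), `rois`, `crowding`, and comparisons
#'   `comparison` (CSA) and `crowding_comparison`.
#' @export
run_csa_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list(); crowd <- list(); roi_rows <- list()
  stage_log <- character(0)
  for (i in seq_along(config$conditions)) {
    cname <- names(config$conditions)[i]
    field <- condition_field(config$conditions[[i]], config, i,
                             make_plane_field)
    grid <- field$grid
    extent <- dim(grid) * grid$voxel_size
    boxes <- tile_rois(extent, box_size = config$roi$box_size,
                       n_boxes = config$roi$n_boxes,
                       exclusion_mask = config$roi$exclusion_mask,
                       mask_pixel_size = config$roi$mask_pixel_size,
                       seed = config$seed + 104729L * i)
    boxes <- cbind(condition = cname, boxes)
    roi_rows[[cname]] <- boxes
    for (b in seq_len(nrow(boxes))) {
      px <- crop_box(grid, boxes[b, ])
      lm <- segment_with(px, config)
      if (n_objects(lm) == 0L) next
      tab <- measure_nuclei(lm)
      tab <- cbind(condition = cname, box = boxes$box[b], tab)
      rows[[paste(cname, b)]] <- tab
      if (nrow(tab) >= 3L) {
        g <- delaunay_graph(tab$centroid_x_um, tab$centroid_y_um,
                            ids = tab$id)
        ci <- crowding_indices(g, tab)
        crowd[[paste(cname, b)]] <- cbind(condition = cname,
                                          box = boxes$box[b], ci)
      }
    }
    n_cond <- sum(vapply(rows[grep(paste0("^", cname, " "), names(rows))],
                         nrow, integer(1)))
    stage_log <- c(stage_log, sprintf("%s: %d nuclei over %d ROI boxes",
                                      cname, n_cond, nrow(boxes)))
  }
  nuclei <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(condition = character(0), csa_um2 = numeric(0))
  crowding <- if (length(crowd))
    do.call(rbind, c(crowd, make.row.names = FALSE)) else
    data.frame(condition = character(0), crowding_index = numeric(0))
  comparison <- compare_conditions(nuclei, "csa_um2", config$policy)
  crowding_ok <- crowding[!is.na(crowding$crowding_index), , drop = FALSE]
  crowding_comparison <- compare_conditions(crowding_ok, "crowding_index",
                                            config$policy)
  bundle <- new_bundle(config,
                       list(nuclei = nuclei,
                            rois = do.call(rbind, c(roi_rows,
                                                    make.row.names = FALSE)),
                            crowding = crowding),
                       comparison, stage_log)
  bundle$crowding_comparison <- crowding_comparison
  maybe_write(bundle, config)
}

crop_box <- function(grid, box) {
  vs <- grid$voxel_size
  ix <- max(1L, floor(box$x0_um / vs[1]) + 1L):min(dim(grid)[1],
                                                   ceiling(box$x1_um / vs[1]))
  iy <- max(1L, floor(box$y0_um / vs[2]) + 1L):min(dim(grid)[2],
                                                   ceiling(box$y1_um / vs[2]))
  voxel_grid(grid$intensities[ix, iy, drop = FALSE], vs, grid$bit_depth)
}

#' Line-scan pipeline: peripheral-enrichment fraction per nucleus
#'
#' For each condition: render the nuclear field and its membrane channel,
#' segment the nuclear stack, and for every surviving nucleus take its
#' mask on the middle z-plane, draw the long axis, sample the membrane
#' profile along it, and compute the peripheral fraction within the margin.
#' Conditions are compared on the per-nucleus fractions.
#'
#' @param config a [run_config()]; each condition should carry `spec` and
#'   `membrane` ([membrane_spec()]).
#' @return a `results_bundle` with table `fractions` (per-nucleus peripheral
#'   fraction, span and flags) and the condition `comparison`.
#' @export
run_linescan_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  stage_log <- character(0)
  for (i in seq_along(config$conditions)) {
    cname <- names(config$conditions)[i]
    field <- condition_field(config$conditions[[i]], config, i,
                             make_nucleus_field)
    if (is.null(field$membrane))
      stop("condition ", cname, " has no membrane channel for the line scan")
    lm <- segment_with(field$grid, config)
    zmid <- (dim(lm)[3] + 1L) %/% 2L
    kept <- 0L
    for (id in seq_len(n_objects(lm))) {
      mask2d <- lm$labels[, , zmid] == id
      if (sum(mask2d) < 20L) next
      seg <- tryCatch(long_axis(mask2d, lm$voxel_size[1:2]),
                      error = function(e) NULL)
      if (is.null(seg)) next
      prof <- tryCatch(
        sample_profile(field$membrane, seg, step = config$linescan$step,
                       mask = mask2d),
        error = function(e) NULL)
      if (is.null(prof) || is.null(prof$edge_positions)) next
      pf <- tryCatch(
        peripheral_fraction(prof, d = config$linescan$margin_um),
        error = function(e) NULL)
      if (is.null(pf)) next
      kept <- kept + 1L
      rows[[paste(cname, id)]] <- data.frame(
        condition = cname, id = id, fraction = pf$value,
        span_um = pf$span_um, flagged = pf$flagged)
    }
    stage_log <- c(stage_log, sprintf(
      "%s: %d nuclei segmented, %d line scans measured", cname,
      n_objects(lm), kept))
  }
  fractions <- if (length(rows))
    do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(condition = character(0), fraction = numeric(0))
  comparison <- compare_conditions(fractions, "fraction", config$policy)
  bundle <- new_bundle(config, list(fractions = fractions), comparison,
                       stage_log)
  maybe_write(bundle, config)
}

maybe_write <- function(bundle, config) {
  if (!is.null(config$out_dir)) write_results_bundle(bundle, config)
  bundle
}

#' Write a results bundle: CSV tables, effective config, text report
#'
#' Each CSV starts with a schema comment line (`# nucmorph table v1 ...`);
#' units are embedded in column names. The effective configuration is written
#' as YAML and a human-readable report summarises stage counts and the group
#' comparison.
#'
#' @param bundle a `results_bundle`.
#' @param config the [run_config()] that produced it.
#' @return the output directory, invisibly.
#' @export
write_results_bundle <- function(bundle, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables))
    write_versioned_csv(bundle$tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  cfg <- config
  cfg$conditions <- lapply(cfg$conditions, function(cd) {
    if (inherits(cd, "field_spec")) unclass(cd) else
      lapply(cd, function(x) if (is.list(x)) unclass(x) else x)
  })
  cfg$policy <- unclass(cfg$policy)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.null(x)) "null" else x), file.path(dir, "config.yaml"))
  rep_lines <- c("nucmorph run report", "-------------------",
                 bundle$stage_log)
  if (!is.null(bundle$comparison))
    rep_lines <- c(rep_lines, "",
                   utils::capture.output(print(bundle$comparison)))
  writeLines(rep_lines, file.path(dir, "report.txt"))
  invisible(dir)
}

write_versioned_csv <- function(df, path) {
  con <- file(path, "w")
  writeLines(paste0("# nucmorph table v1; columns: ",
                    paste(names(df), collapse = ",")), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Read a versioned nucmorph CSV table
#' @param path file written by [write_results_bundle()].
#' @return data frame.
#' @export
read_versioned_csv <- function(path) read.csv(path, comment.char = "#")

#' Deterministic hash of a results bundle's tables
#'
#' MD5 over the concatenated CSV text of every table, for end-to-end
#' determinism checks: identical config + seed must give identical hashes.
#'
#' @param bundle a `results_bundle`.
#' @return character MD5 hash.
#' @export
bundle_hash <- function(bundle) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  for (nm in names(bundle$tables)) {
    writeLines(nm, con)
    write.csv(format(bundle$tables[[nm]], digits = 15), con,
              row.names = FALSE)
  }
  close(con)
  unname(tools::md5sum(tmp))
}
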
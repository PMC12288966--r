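#' Calibrated intensity image (2D plane or 3D stack)
#'
#' The container consumed by every imaging stage. Intensities are stored as a
#' numeric array indexed `[x, y]` (plane) or `[x, y, z]` (stack); the physical
#' size of a voxel is carried alongside so that all downstream measurements are
#' in micrometres. Values are expected to lie within the declared bit depth
#' (8-bit: 0..255, 16-bit: 0..65535).
#'
#' @param intensities numeric matrix (2D) or 3D array of intensities.
#' @param voxel_size numeric, micrometres per voxel along each axis:
#'   `c(dx, dy)` for a plane, `c(dx, dy, dz)` for a stack.
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(matrix(0, 16, 16), voxel_size = c(0.5, 0.5))
#' dim(g)
#' @export
voxel_grid <- function(intensities, voxel_size, bit_depth = 8L) {
  if (!is.array(intensities) && !is.matrix(intensities))
    stop("`intensities` must be a matrix or array")
  nd <- length(dim(intensities))
  if (!nd %in% c(2L, 3L)) stop("`intensities` must be 2D or 3D")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != nd)
    stop("`voxel_size` must have one entry per image axis (got ",
         length(voxel_size), " for a ", nd, "D image)")
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("all voxel dimensions must be positive")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(
    list(intensities = intensities,
         voxel_size = voxel_size,
         bit_depth = as.integer(bit_depth)),
    class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$intensities)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid> %s voxels, %s um/voxel, %d-bit, range [%g, %g]\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x "),
              x$bit_depth,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Physical volume (or area) of one voxel in um^3 (um^2 for planes)
#' @param grid a [voxel_grid] or [label_map].
#' @return scalar, product of the per-axis voxel dimensions.
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

is_2d <- function(grid) length(dim(grid$intensities %||% grid$labels)) == 2L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer-labelled segmentation on a calibrated lattice
#'
#' Wraps an integer array the same shape as the source grid, where 0 is
#' background and labels run contiguously from 1. `provenance` records every
#' parameter that produced the map (threshold, connectivity, filters), so a
#' result table can always be traced back to its settings.
#'
#' @param labels integer matrix/array, 0 = background.
#' @param voxel_size micrometres per voxel along each axis.
#' @param provenance named list of processing parameters.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size, provenance = list()) {
  nd <- length(dim(labels))
  if (!nd %in% c(2L, 3L)) stop("`labels` must be 2D or 3D")
  if (length(voxel_size) != nd)
    stop("`voxel_size` must have one entry per axis")
  structure(
    list(labels = labels,
         voxel_size = as.numeric(voxel_size),
         provenance = provenance),
    class = "label_map")
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' Number of labelled objects in a label map
#' @param map a [label_map].
#' @return integer count of distinct nonzero labels.
#' @export
n_objects <- function(map) {
  if (length(map$labels) == 0) return(0L)
  m <- max(map$labels)
  if (m == 0) 0L else length(unique(map$labels[map$labels > 0L]))
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s voxels, %d objects\n",
              paste(dim(x), collapse = " x "), n_objects(x)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' Read a calibrated image stack from a multi-page TIFF
#'
#' Pages are z-planes. Calibration is taken from `voxel_size`, or, when
#' `NULL`, from a YAML sidecar `<path>.yaml` with a `voxel_size_um` key (as
#' written by [write_stack()]).
#'
#' @param path TIFF file path.
#' @param voxel_size micrometres per voxel `c(dx, dy, dz)` (or `c(dx, dy)` for
#'   a single page read as a plane), or `NULL` to read the sidecar.
#' @param bit_depth 8 or 16; intensities are rescaled from the \[0,1\] range
#'   `tiff` returns to this integer range.
#' @return a [voxel_grid].
#' @export
read_stack <- function(path, voxel_size = NULL, bit_depth = 8L) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (is.null(voxel_size)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("missing calibration for ", path,
           ": supply `voxel_size` or a sidecar ", sidecar)
    meta <- yaml::read_yaml(sidecar)
    voxel_size <- as.numeric(meta$voxel_size_um)
    bit_depth <- as.integer(meta$bit_depth %||% bit_depth)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 2^bit_depth - 1
  # readTIFF returns row = y, col = x in [0, 1]; transpose to [x, y]
  planes <- lapply(pages, function(p) round(t(p) * scale))
  if (length(planes) == 1L && length(voxel_size) == 2L) {
    arr <- planes[[1L]]
  } else {
    arr <- array(unlist(planes),
                 dim = c(dim(planes[[1L]]), length(planes)))
    if (length(voxel_size) == 2L) voxel_size <- c(voxel_size, 1)
  }
  voxel_grid(arr, voxel_size, bit_depth)
}

#' Write a calibrated stack as a multi-page TIFF plus a YAML sidecar
#'
#' @param grid a [voxel_grid].
#' @param path output TIFF path; the sidecar is written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  scale <- 2^grid$bit_depth - 1
  arr <- pmax(pmin(grid$intensities, scale), 0) / scale
  planes <- if (is_2d(grid)) list(t(arr)) else
    lapply(seq_len(dim(arr)[3]), function(k) t(arr[, , k]))
  tiff::writeTIFF(planes, path, bits.per.sample = grid$bit_depth)
  yaml::write_yaml(
    list(voxel_size_um = as.numeric(grid$voxel_size),
         bit_depth = grid$bit_depth,
         axes = if (is_2d(grid)) "xy" else "xyz"),
    paste0(path, ".yaml"))
  invisible(path)
}
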
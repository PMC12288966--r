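#' Randomly tile non-overlapping ROI boxes over a large plane
#'
#' Samples `n_boxes` axis-aligned square boxes of side `box_size` um uniformly
#' inside `extent`, by rejection: a candidate is kept if it lies fully in
#' bounds, does not overlap an already accepted box, and (when an exclusion
#' mask is given) contains no excluded pixel. Boxes are half-open
#' `[x0, x0+box) x [y0, y0+box)`. After `max_attempts` failures the overlap
#' constraint is relaxed with a warning; if the exclusion mask leaves no room
#' at all, an error is raised. Deterministic given `seed`.
#'
#' @param extent plane extent `c(x, y)` in um.
#' @param box_size box side in um (default 1500).
#' @param n_boxes number of boxes (default 8).
#' @param exclusion_mask optional logical matrix (`TRUE` = excluded), covering
#'   `extent` at pixel size `mask_pixel_size`.
#' @param mask_pixel_size um per mask pixel, `c(dx, dy)`.
#' @param seed integer seed.
#' @param max_attempts rejection attempts per box before relaxing/failing.
#' @return data frame with columns `box`, `x0_um`, `y0_um`, `x1_um`, `y1_um`.
#' @export
tile_rois <- function(extent, box_size = 1500, n_boxes = 8L,
                      exclusion_mask = NULL, mask_pixel_size = NULL,
                      seed = 1L, max_attempts = 10000L) {
  if (any(extent < box_size))
    stop("extent ", paste(extent, collapse = " x "),
         " um is smaller than the ROI box (", box_size, " um)")
  if (!is.null(exclusion_mask) && is.null(mask_pixel_size))
    stop("`mask_pixel_size` is required with an exclusion mask")
  withr::with_seed(seed, {
    acc <- matrix(numeric(0), 0, 2)
    for (b in seq_len(n_boxes)) {
      placed <- FALSE
      relax <- FALSE
      att <- 0L
      while (!placed) {
        att <- att + 1L
        if (att > max_attempts) {
          if (!relax) {
            warning("could not place box ", b,
                    " without overlap; allowing overlap")
            relax <- TRUE
            att <- 0L
          } else {
            stop("could not place box ", b, " outside the exclusion mask ",
                 "after ", max_attempts, " attempts")
          }
        }
        p <- runif(2) * (extent - box_size)
        if (!relax && nrow(acc) &&
            any(abs(acc[, 1] - p[1]) < box_size &
                abs(acc[, 2] - p[2]) < box_size)) next
        if (!is.null(exclusion_mask)) {
          ix <- (floor(p[1] / mask_pixel_size[1]) + 1L):
            min(ceiling((p[1] + box_size) / mask_pixel_size[1]),
                nrow(exclusion_mask))
          iy <- (floor(p[2] / mask_pixel_size[2]) + 1L):
            min(ceiling((p[2] + box_size) / mask_pixel_size[2]),
                ncol(exclusion_mask))
          if (any(exclusion_mask[ix, iy])) next
        }
        acc <- rbind(acc, p)
        placed <- TRUE
      }
    }
    data.frame(box = seq_len(n_boxes),
               x0_um = acc[, 1], y0_um = acc[, 2],
               x1_um = acc[, 1] + box_size, y1_um = acc[, 2] + box_size)
  })
}

#' 2D Delaunay triangulation with edge lengths
#'
#' Triangulates nucleus centroids and returns the edge list with Euclidean
#' lengths in um — the internuclear-distance graph. Fewer than two points
#' give an empty graph; collinear (degenerate) inputs fall back to a
#' nearest-neighbour chain, flagged in the result.
#'
#' @param x,y centroid coordinates in um (or `x` a 2-column matrix).
#' @param ids optional node ids (default `seq_along(x)`).
#' @return list of class `delaunay_graph` with `edges` (data frame `i`, `j`,
#'   `length_um`, using `ids`), `n` nodes, and `degenerate` flag.
#' @export
delaunay_graph <- function(x, y = NULL, ids = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    y <- x[, 2]
    x <- x[, 1]
  }
  n <- length(x)
  if (is.null(ids)) ids <- seq_len(n)
  empty <- data.frame(i = integer(0), j = integer(0), length_um = numeric(0))
  if (n < 2L)
    return(structure(list(edges = empty, n = n, degenerate = FALSE),
                     class = "delaunay_graph"))
  if (n == 2L || is_collinear(x, y)) {
    ord <- order(x, y)
    e <- cbind(ord[-n], ord[-1L])
    edges <- data.frame(i = ids[e[, 1]], j = ids[e[, 2]],
                        length_um = sqrt((x[e[, 1]] - x[e[, 2]])^2 +
                                           (y[e[, 1]] - y[e[, 2]])^2))
    return(structure(list(edges = edges, n = n, degenerate = n > 2L),
                     class = "delaunay_graph"))
  }
  dxy <- deldir::deldir(x, y, suppressMsge = TRUE)
  sg <- dxy$delsgs
  # lengths from the original coordinates: deldir rescales internally and
  # its reported segment endpoints lose ~1e-8 of relative precision
  i1 <- pmin(sg$ind1, sg$ind2)
  i2 <- pmax(sg$ind1, sg$ind2)
  edges <- data.frame(i = ids[i1], j = ids[i2],
                      length_um = sqrt((x[i1] - x[i2])^2 + (y[i1] - y[i2])^2))
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, degenerate = FALSE),
            class = "delaunay_graph")
}

is_collinear <- function(x, y, tol = 1e-9) {
  if (length(x) < 3L) return(FALSE)
  dx <- x - x[1]; dy <- y - y[1]
  cross <- dx[2] * dy - dy[2] * dx
  scale <- max(abs(c(dx, dy)), 1)
  all(abs(cross) <= tol * scale^2)
}

#' @export
print.delaunay_graph <- function(x, ...) {
  cat(sprintf("<delaunay_graph> %d nodes, %d edges%s\n", x$n, nrow(x$edges),
              if (x$degenerate) " (degenerate: nearest-neighbour chain)" else ""))
  invisible(x)
}

#' Size-corrected crowding index per nucleus
#'
#' For each nucleus, the mean (or median) length of its incident Delaunay
#' edges — the internuclear distance — divided by its equivalent diameter.
#' The ratio is invariant under joint spatial scaling of positions and sizes,
#' which is what makes it a crowding measure free of nuclear-size
#' confounding. Nuclei without Delaunay neighbours or without a diameter are
#' flagged and excluded from summaries.
#'
#' @param graph a [delaunay_graph()] whose node ids match `records$id`.
#' @param records data frame with columns `id` and `equivalent_diameter_um`
#'   (e.g. from [measure_nuclei()]).
#' @param summary `"mean"` (default) or `"median"` of incident edge lengths.
#' @return data frame with `id`, `mean_edge_um`, `equivalent_diameter_um`,
#'   `crowding_index`, `flag`.
#' @export
crowding_indices <- function(graph, records, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(inherits(graph, "delaunay_graph"))
  if (!all(c("id", "equivalent_diameter_um") %in% names(records)))
    stop("`records` needs columns `id` and `equivalent_diameter_um`")
  fun <- if (summary == "mean") mean else median
  ids <- records$id
  inc <- rbind(data.frame(id = graph$edges$i, len = graph$edges$length_um),
               data.frame(id = graph$edges$j, len = graph$edges$length_um))
  agg <- if (nrow(inc)) vapply(split(inc$len, inc$id), fun, numeric(1)) else
    setNames(numeric(0), character(0))
  mean_edge <- agg[as.character(ids)]
  diam <- records$equivalent_diameter_um
  flag <- is.na(mean_edge) | !is.finite(diam) | diam <= 0
  data.frame(id = ids,
             mean_edge_um = unname(mean_edge),
             equivalent_diameter_um = diam,
             crowding_index = ifelse(flag, NA_real_,
                                     unname(mean_edge) / diam),
             flag = flag)
}
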
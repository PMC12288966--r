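# Independent oracles used across the suite. These are deliberately naive
# (brute force) and share no code with the package internals they check.

# Flood-fill connected-component labelling, plain R queue-based BFS.
flood_fill_labels <- function(mask, full = FALSE) {
  dims <- dim(mask)
  nd <- length(dims)
  labels <- array(0L, dims)
  nbhd <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  man <- rowSums(abs(nbhd))
  nbhd <- nbhd[if (full) man > 0 else man == 1, , drop = FALSE]
  nxt <- 0L
  idx_all <- which(mask)
  for (s in idx_all) {
    if (labels[s] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(s, dims)[1, ])
    labels[s] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (r in seq_len(nrow(nbhd))) {
        w <- v + nbhd[r, ]
        if (any(w < 1L) || any(w > dims)) next
        wi <- w[1]
        mult <- 1L
        for (j in seq_len(nd - 1)) {
          mult <- mult * dims[j]
          wi <- wi + (w[j + 1] - 1L) * mult
        }
        if (mask[wi] && labels[wi] == 0L) {
          labels[wi] <- nxt
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  labels
}

# Canonical relabelling by first occurrence in linear scan order, so two
# labelings of the same partition compare equal.
canon_labels <- function(labels) {
  l <- as.integer(labels)
  u <- unique(l[l > 0L])
  m <- integer(max(c(l, 0L)) + 1L)
  m[u + 1L] <- seq_along(u)
  out <- ifelse(l > 0L, m[l + 1L], 0L)
  dim(out) <- dim(labels)
  out
}

# Brute-force Delaunay edge set by the empty-circumcircle criterion over all
# point triples. O(n^4); fine for n <= 30.
delaunay_edges_oracle <- function(x, y, tol = 1e-9) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  trips <- utils::combn(n, 3)
  for (t in seq_len(ncol(trips))) {
    i <- trips[1, t]; j <- trips[2, t]; k <- trips[3, t]
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear triple
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 - tol)))
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  if (!nrow(edges)) return(edges)
  edges <- t(apply(edges, 1, sort))
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-")

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n1+n2, n1) group assignments of the pooled ranks.
mw_exact_p_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  cdf_lo <- mean(us <= obs_u)
  cdf_hi <- mean(us >= obs_u)
  min(1, 2 * min(cdf_lo, cdf_hi))
}

# Small deterministic test grid builder.
grid_from <- function(arr, voxel = rep(0.5, length(dim(arr))), bits = 8L)
  voxel_grid(arr, voxel, bits)

# A single ellipsoidal nucleus rendered at the exact centre of a field,
# with the same ground-truth layout make_nucleus_field() produces. No RNG.
centered_nucleus <- function(radii = c(6, 6, 6), extent = c(26, 26, 18),
                             voxel = 0.25, fg = 200) {
  truth <- data.frame(
    id = 1L, population = 1L,
    cx_um = extent[1] / 2, cy_um = extent[2] / 2, cz_um = extent[3] / 2,
    a_um = radii[1], b_um = radii[2], c_um = radii[3], angle_rad = 0,
    volume_um3 = 4 / 3 * pi * prod(radii))
  dims <- as.integer(round(extent / voxel))
  arr <- array(0, dims)
  idx <- nucmorph:::ellipsoid_voxels(dims, rep(voxel, 3), truth[1, ], 3L)
  arr[idx] <- fg
  list(grid = voxel_grid(arr, rep(voxel, 3)), truth = truth, idx = idx)
}

# Hexagonal (triangular) lattice points with spacing s; returns coordinates
# and a logical interior marker (not on the outer ring of rows/columns).
hex_lattice <- function(nrow = 6, ncol = 6, s = 30) {
  pts <- do.call(rbind, lapply(seq_len(nrow), function(r) {
    off <- if (r %% 2 == 0) s / 2 else 0
    cbind(x = seq_len(ncol) * s + off,
          y = r * s * sqrt(3) / 2,
          row = r, col = seq_len(ncol))
  }))
  interior <- pts[, "row"] > 1 & pts[, "row"] < nrow &
    pts[, "col"] > 1 & pts[, "col"] < ncol
  list(x = pts[, "x"], y = pts[, "y"], interior = interior)
}
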
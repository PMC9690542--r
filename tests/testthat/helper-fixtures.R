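# Shared fixtures: all test data is generated in code.

# Compact phantom spec (reduced structure sizes) that renders in well
# under a second on a small grid.
compact_sizes <- list(vb_semiaxes = c(10, 6, 8), vd_semiaxes = c(10, 3.2, 8))

tiny_spec <- function(seed = 2, n_vb = 3, grid = c(96, 96, 24), ...) {
  do.call(phantom_spec, c(list(n_vertebral_bodies = n_vb, grid_shape = grid,
                               seed = seed), compact_sizes, list(...)))
}

tiny_phantom_args <- function(...) c(compact_sizes, list(...))

tiny_network <- function(depth = 2, features = c(4, 8), seed = 5) {
  build_network(network_spec(depth = depth, features = features), seed = seed)
}

# O(n^3) brute-force convex hull area: a directed pair (i, j) is a hull
# edge iff every other point lies on one side of the line through it;
# hull vertices are the edge endpoints, angularly sorted for the
# shoelace sum.  Independent of grDevices::chull.
hull_area_oracle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- logical(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- pts[j, 1] - pts[i, 1]
    dy <- pts[j, 2] - pts[i, 2]
    cr <- dx * (pts[, 2] - pts[i, 2]) - dy * (pts[, 1] - pts[i, 1])
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  hp <- pts[on_hull, , drop = FALSE]
  if (nrow(hp) < 3) return(0)
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Naive per-voxel confusion counting (independent oracle).
confusion_oracle <- function(pred, truth, cls) {
  tp <- 0L; fp <- 0L; fn <- 0L
  d <- dim(pred)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- pred[i, j, k] == cls
    t <- truth[i, j, k] == cls
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
  }
  list(TP = tp, FP = fp, FN = fn)
}
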
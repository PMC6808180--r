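# Shared fixtures: small, fast configurations used across test files.

small_cohort_config <- function(seed = 1L, sd = 0.5, sizes = c(40, 35, 38, 37)) {
  cohort_config(cluster_sizes = sizes, within_cluster_sd = sd, seed = seed)
}

fast_som_config <- function(seed = 1L, ...) {
  som_config(grid_rows = 6, grid_cols = 6, seed = seed, ...)
}

# Brute-force BFS hop distances on an adjacency matrix (independent of igraph).
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] & is.infinite(d[s, ]))
        d[s, nb] <- lev
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Exhaustive 2D KS oracle: scans every grid node as origin, all four
# quadrant orientations, via explicit loops.
ks2d_oracle <- function(a, b, grid_x, grid_y) {
  best <- 0
  for (x0 in grid_x) for (y0 in grid_y) {
    for (qx in c(TRUE, FALSE)) for (qy in c(TRUE, FALSE)) {
      ina <- mean((if (qx) a[, 1] <= x0 else a[, 1] > x0) &
                  (if (qy) a[, 2] <= y0 else a[, 2] > y0))
      inb <- mean((if (qx) b[, 1] <= x0 else b[, 1] > x0) &
                  (if (qy) b[, 2] <= y0 else b[, 2] > y0))
      best <- max(best, abs(ina - inb))
    }
  }
  best
}

# One Lloyd update with fixed centroids as an independent oracle for
# batch_cycle at nd = 0: each centroid moves to the mean of the points
# nearest to it (ties to the lowest index), or stays if it captures none.
lloyd_step <- function(centers, x) {
  assign <- apply(x, 1, function(p) {
    d <- colSums((t(centers) - p)^2)
    which.min(d)
  })
  out <- centers
  for (i in seq_len(nrow(centers))) {
    pts <- x[assign == i, , drop = FALSE]
    if (nrow(pts) > 0) out[i, ] <- colMeans(pts)
  }
  out
}
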
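#' Configuration for batch self-organizing map training
#'
#' Defaults follow the classical batch-SOM recipe for a cohort of a few
#' hundred observations: a 10 x 10 grid (about five times the square root of
#' the number of observations), hexagonal topology with link (hop-count)
#' grid distance, an ordering phase of 5 batch cycles shrinking the
#' neighborhood from the initial size down to 1, and a single fine-tuning
#' cycle with neighborhood below 1 (so each node is updated only from the
#' inputs for which it is the best matching unit, BMU).
#'
#' @param grid_rows,grid_cols Grid dimensions (product >= 2).
#' @param topology \code{"hexagonal"} or \code{"rectangular"}.
#' @param grid_metric \code{"link"} (hop count), \code{"euclidean"}, or
#'   \code{"chebyshev"}.
#' @param initial_neighborhood Initial neighborhood size INS (>= 1).
#' @param ordering_steps Number n of ordering cycles.
#' @param finetune_steps Number of fine-tuning cycles.
#' @param finetune_neighborhood Neighborhood during fine tuning; must be < 1.
#' @param init_jitter_sd Standard deviation of Gaussian jitter added to the
#'   PCA-plane initialization. A small positive value (default 0.05) makes
#'   repeated retrainings stochastically independent, which the consensus
#'   clustering relies on; set 0 for fully deterministic training.
#' @param seed Integer seed for the jitter.
#' @return An object of class \code{som_config}.
#' @export
som_config <- function(grid_rows = 10, grid_cols = 10,
                       topology = c("hexagonal", "rectangular"),
                       grid_metric = c("link", "euclidean", "chebyshev"),
                       initial_neighborhood = 3,
                       ordering_steps = 5,
                       finetune_steps = 1,
                       finetune_neighborhood = 0,
                       init_jitter_sd = 0.05,
                       seed = 1L) {
  topology <- match.arg(topology)
  grid_metric <- match.arg(grid_metric)
  if (grid_rows * grid_cols < 2) stop("grid must have at least 2 nodes")
  if (initial_neighborhood < 1) stop("initial_neighborhood must be >= 1")
  if (finetune_neighborhood >= 1) stop("finetune_neighborhood must be < 1")
  if (init_jitter_sd < 0) stop("init_jitter_sd must be nonnegative")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         topology = topology, grid_metric = grid_metric,
         initial_neighborhood = initial_neighborhood,
         ordering_steps = as.integer(ordering_steps),
         finetune_steps = as.integer(finetune_steps),
         finetune_neighborhood = finetune_neighborhood,
         init_jitter_sd = init_jitter_sd, seed = as.integer(seed)),
    class = "som_config"
  )
}

# Node layout in row-major order (node = (row-1)*grid_cols + col).
# Hexagonal topology offsets odd rows by half a unit and compresses row
# spacing to sqrt(3)/2 so that all six neighbors sit at unit distance.
som_node_positions <- function(config) {
  r <- rep(seq_len(config$grid_rows), each = config$grid_cols)
  c_ <- rep(seq_len(config$grid_cols), times = config$grid_rows)
  if (config$topology == "hexagonal") {
    x <- c_ + 0.5 * ((r - 1) %% 2)
    y <- (r - 1) * sqrt(3) / 2
  } else {
    x <- c_
    y <- r
  }
  cbind(row = r, col = c_, x = x, y = y)
}

#' Pairwise grid distances between SOM nodes
#'
#' Distances on the node layout under the configured metric: Euclidean on
#' node positions, Chebyshev (max coordinate difference), or link distance
#' (minimum hop count on the grid adjacency graph, where nodes at unit
#' position distance are adjacent).
#'
#' @param config A \code{som_config}.
#' @return Symmetric node x node matrix with zero diagonal.
#' @export
grid_distances <- function(config) {
  pos <- som_node_positions(config)
  xy <- pos[, c("x", "y"), drop = FALSE]
  d_euc <- as.matrix(stats::dist(xy))
  dimnames(d_euc) <- NULL
  switch(config$grid_metric,
    euclidean = d_euc,
    chebyshev = {
      dx <- abs(outer(xy[, 1], xy[, 1], "-"))
      dy <- abs(outer(xy[, 2], xy[, 2], "-"))
      pmax(dx, dy)
    },
    link = {
      adj <- d_euc <= 1 + 1e-6 & d_euc > 0
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      d <- igraph::distances(g)
      dimnames(d) <- NULL
      d
    })
}

#' PCA-plane initialization of node weights
#'
#' Places the initial node weights on the plane spanned by the first two
#' principal components of the input data, through the data mean: node
#' weights vary linearly along PC1 across grid rows and along PC2 across
#' grid columns, with spans proportional to the square roots of the two
#' leading eigenvalues of the sample covariance. Optional Gaussian jitter
#' (seeded) perturbs the plane.
#'
#' @param data A \code{cohort_matrix} or numeric matrix (children x
#'   measures); only cognitive measures are used for a cohort.
#' @param config A \code{som_config}.
#' @return Node x measure weight matrix.
#' @export
init_weights_pca <- function(data, config) {
  x <- if (inherits(data, "cohort_matrix")) cognitive_scores(data) else as.matrix(data)
  if (nrow(x) < 3) stop("need at least 3 observations")
  if (ncol(x) < 2) stop("need at least 2 measures")
  if (!all(is.finite(x))) stop("data must be finite")
  mu <- colMeans(x)
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  v1 <- eg$vectors[, 1]
  if (length(lam) < 2 || lam[2] <= 1e-12 * max(lam[1], 1)) {
    warning("data has fewer than 2 nonzero principal components; ",
            "initializing along the leading component only")
    v2 <- rep(0, ncol(x))
    lam2 <- 0
  } else {
    v2 <- eg$vectors[, 2]
    lam2 <- lam[2]
  }
  lin <- function(k) if (k == 1) 0 else seq(-1, 1, length.out = k)
  a_row <- lin(config$grid_rows)
  a_col <- lin(config$grid_cols)
  pos <- som_node_positions(config)
  w <- matrix(mu, nrow(pos), ncol(x), byrow = TRUE) +
    outer(a_row[pos[, "row"]] * sqrt(lam[1]), v1) +
    outer(a_col[pos[, "col"]] * sqrt(lam2), v2)
  if (config$init_jitter_sd > 0) {
    set.seed(config$seed)
    w <- w + matrix(stats::rnorm(length(w), sd = config$init_jitter_sd),
                    nrow(w), ncol(w))
  }
  colnames(w) <- colnames(x)
  w
}

#' Best matching unit for a single input vector
#'
#' The node whose weight vector has the smallest Euclidean distance to
#' \code{x}; ties are broken toward the lowest node index.
#'
#' @param weights Node x measure weight matrix.
#' @param x Numeric vector of length \code{ncol(weights)}.
#' @return Integer node index.
#' @export
find_bmu <- function(weights, x) {
  if (length(x) != ncol(weights))
    stop("input dimension ", length(x), " does not match measure count ",
         ncol(weights))
  d2 <- rowSums(sweep(weights, 2, x)^2)
  which.min(d2)
}

# Vectorized BMU assignment for a data matrix: argmin_i ||w_i||^2 - 2 w_i.x
# per child, ties toward the lowest node index.
som_bmus <- function(weights, x) {
  w2 <- rowSums(weights^2)
  score <- w2 - 2 * (weights %*% t(x))   # node x child
  max.col(-t(score), ties.method = "first")
}

#' One batch SOM update cycle
#'
#' Every input is mapped to its BMU under the pre-cycle weights; each node's
#' new weight is the mean of all inputs whose BMU lies within grid distance
#' \code{nd} of it (a bubble neighborhood). All nodes are updated
#' concurrently; a node whose neighborhood captures no inputs keeps its
#' previous weights. With \code{nd = 0} this is exactly one Lloyd (k-means)
#' update step with nodes as centroids.
#'
#' @param weights Node x measure matrix (pre-cycle).
#' @param data Input matrix (children x measures) or \code{cohort_matrix}.
#' @param nd Neighborhood size (>= 0).
#' @param grid_dist Node x node grid distance matrix.
#' @return Updated node x measure weight matrix.
#' @export
batch_cycle <- function(weights, data, nd, grid_dist) {
  x <- if (inherits(data, "cohort_matrix")) cognitive_scores(data) else as.matrix(data)
  if (nrow(x) == 0) stop("empty data")
  if (nd < 0) stop("nd must be >= 0")
  n_nodes <- nrow(weights)
  bmu <- som_bmus(weights, x)
  counts <- tabulate(bmu, n_nodes)
  sums <- matrix(0, n_nodes, ncol(x))
  agg <- rowsum(x, group = bmu)
  sums[as.integer(rownames(agg)), ] <- agg
  nb <- (grid_dist <= nd) * 1
  num <- nb %*% sums
  den <- as.numeric(nb %*% counts)
  new_w <- weights
  upd <- den > 0
  new_w[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  colnames(new_w) <- colnames(weights)
  new_w
}

#' Neighborhood-size schedule for batch training
#'
#' During the ordering phase the neighborhood size decreases linearly with
#' cycle number t over n steps, \code{ND(t) = 1 + INS * (1 - t/n)}, reaching
#' exactly 1 at the final ordering cycle; the fine-tuning phase then holds
#' the neighborhood fixed below 1.
#'
#' @param config A \code{som_config}.
#' @return Numeric vector of ND values, one per training cycle.
#' @export
neighborhood_schedule <- function(config) {
  n <- config$ordering_steps
  t <- seq_len(n)
  c(1 + config$initial_neighborhood * (1 - t / n),
    rep(config$finetune_neighborhood, config$finetune_steps))
}

#' Train a batch self-organizing map
#'
#' Initializes node weights on the PCA plane (with seeded jitter), runs one
#' batch update cycle per schedule entry, and assigns each child its final
#' BMU. Fully deterministic given data, config, and seed.
#'
#' @param data A \code{cohort_matrix} (cognitive measures are used) or a
#'   plain numeric matrix.
#' @param config A \code{som_config}.
#' @return An object of class \code{trained_som} with elements
#'   \code{weights} (node x measure), \code{node_coords} (node grid
#'   row/col and layout positions), \code{schedule_trace}, \code{bmu}
#'   (per-child node index), \code{quantization_error} (mean child-to-BMU
#'   distance after each cycle), and the \code{config}.
#' @export
train_som <- function(data, config = som_config()) {
  x <- if (inherits(data, "cohort_matrix")) cognitive_scores(data) else as.matrix(data)
  gd <- grid_distances(config)
  w <- init_weights_pca(x, config)
  sched <- neighborhood_schedule(config)
  qe <- numeric(length(sched))
  for (i in seq_along(sched)) {
    w <- batch_cycle(w, x, sched[i], gd)
    bmu_i <- som_bmus(w, x)
    qe[i] <- mean(sqrt(rowSums((x - w[bmu_i, , drop = FALSE])^2)))
  }
  bmu <- som_bmus(w, x)
  names(bmu) <- rownames(x)
  structure(
    list(weights = w,
         node_coords = som_node_positions(config),
         schedule_trace = sched,
         bmu = bmu,
         quantization_error = qe,
         config = config),
    class = "trained_som"
  )
}

#' @export
print.trained_som <- function(x, ...) {
  cat("trained_som:", x$config$grid_rows, "x", x$config$grid_cols,
      x$config$topology, "grid,", ncol(x$weights), "measures,",
      length(x$bmu), "children mapped\n")
  cat("  final quantization error:",
      signif(utils::tail(x$quantization_error, 1), 4), "\n")
  invisible(x)
}

#' Per-measure weight planes
#'
#' One grid-shaped matrix per measure, holding that measure's node weights:
#' the standard component-plane view of a trained map.
#'
#' @param som A \code{trained_som}.
#' @return Named list of \code{grid_rows x grid_cols} matrices.
#' @export
weight_planes <- function(som) {
  cfg <- som$config
  lapply(stats::setNames(seq_len(ncol(som$weights)), colnames(som$weights)),
         function(j) {
           matrix(som$weights[, j], cfg$grid_rows, cfg$grid_cols, byrow = TRUE)
         })
}

#' Correlations between weight planes
#'
#' Pearson correlation between the node-weight columns of each pair of
#' measures. Measures whose planes correlate highly discriminate children in
#' similar ways across the map.
#'
#' @param som A \code{trained_som}.
#' @return Symmetric measure x measure correlation matrix; entries involving
#'   a zero-variance plane are \code{NA} (with a warning naming the measure).
#' @export
weight_plane_correlations <- function(som) {
  w <- som$weights
  sds <- apply(w, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance weight plane(s): ",
            paste(colnames(w)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  suppressWarnings(stats::cor(w))
}

#' Grid coordinates of each child's BMU
#'
#' @param som A \code{trained_som}.
#' @return Integer matrix (children x 2) of grid row/col positions.
#' @export
bmu_coordinates <- function(som) {
  som$node_coords[som$bmu, c("row", "col"), drop = FALSE]
}
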
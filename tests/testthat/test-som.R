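test_that("grid distances satisfy basic metric properties", {
  for (metric in c("link", "euclidean", "chebyshev")) {
    cfg <- som_config(grid_rows = 4, grid_cols = 3, topology = "rectangular",
                      grid_metric = metric)
    d <- grid_distances(cfg)
    expect_identical(dim(d), c(12L, 12L))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d[upper.tri(d)] > 0))
  }
})

test_that("small rectangular grids have the expected distances", {
  d12 <- grid_distances(som_config(1, 2, "rectangular", "link"))
  expect_equal(d12[1, 2], 1)
  d33 <- grid_distances(som_config(3, 3, "rectangular", "chebyshev"))
  expect_equal(d33[1, 9], 2)  # corner to opposite corner
  d33e <- grid_distances(som_config(3, 3, "rectangular", "euclidean"))
  expect_equal(d33e[1, 9], 2 * sqrt(2))
})

test_that("hexagonal link distances equal BFS hop counts", {
  cfg <- som_config(10, 10, "hexagonal", "link")
  d <- grid_distances(cfg)
  pos <- phenosom:::som_node_positions(cfg)
  d_euc <- as.matrix(dist(pos[, c("x", "y")]))
  adj <- d_euc <= 1 + 1e-6 & d_euc > 0
  expect_equal(unname(d), unname(bfs_distances(adj)))
  # interior hexagonal nodes have exactly six unit-distance neighbors
  expect_equal(sum(adj[12, ]), 6)
})

test_that("PCA initialization spans the leading principal plane", {
  set.seed(4)
  # data on an exact 2D plane in 5-measure space
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  x <- matrix(rnorm(200), 100, 2) %*% t(basis) +
    matrix(rep(c(1, 2, 3, 4, 5), each = 100), 100, 5)
  colnames(x) <- paste0("m", 1:5)
  cfg <- som_config(5, 4, init_jitter_sd = 0)
  w <- init_weights_pca(x, cfg)
  # residual of node weights to the data plane (through the mean) is 0
  centered <- sweep(w, 2, colMeans(x))
  resid <- centered - centered %*% basis %*% t(basis)
  expect_lt(max(abs(resid)), 1e-10)
  # grand mean of the node weights equals the data mean
  expect_lt(max(abs(colMeans(w) - colMeans(x))), 1e-10)
})

test_that("initial weight spans scale with sqrt of leading eigenvalues", {
  set.seed(7)
  x <- cbind(rnorm(500, sd = 3), rnorm(500, sd = 1))
  colnames(x) <- c("a", "b")
  eg <- eigen(cov(x), symmetric = TRUE)   # independent eigenvalue route
  cfg <- som_config(8, 8, init_jitter_sd = 0)
  w <- init_weights_pca(x, cfg)
  centered <- sweep(w, 2, colMeans(x))
  r1 <- diff(range(centered %*% eg$vectors[, 1]))
  r2 <- diff(range(centered %*% eg$vectors[, 2]))
  expect_equal(r1 / r2, sqrt(eg$values[1] / eg$values[2]), tolerance = 1e-8)
})

test_that("rank-deficient data falls back to the leading component", {
  x <- cbind(seq_len(50), 2 * seq_len(50))  # rank 1
  colnames(x) <- c("a", "b")
  expect_warning(w <- init_weights_pca(x, som_config(3, 3, init_jitter_sd = 0)),
                 "nonzero principal components")
  expect_true(all(is.finite(w)))
})

test_that("find_bmu returns the exact nearest node with low-index ties", {
  w <- matrix(c(0, 0, 1, 1, 0, 0), 3, 2, byrow = TRUE)
  expect_equal(find_bmu(w, c(1, 1)), 2L)
  expect_equal(find_bmu(w, c(0, 0)), 1L)   # tie between nodes 1 and 3
  expect_error(find_bmu(w, c(1, 2, 3)), "dimension")
})

test_that("find_bmu matches an exhaustive scan on random instances", {
  set.seed(11)
  for (rep in 1:50) {
    w <- matrix(rnorm(100 * 7), 100, 7)
    x <- rnorm(7)
    d <- apply(w, 1, function(r) sum((r - x)^2))
    expect_identical(find_bmu(w, x), which.min(d))
  }
  # vectorized assignment agrees with per-vector find_bmu
  x_many <- matrix(rnorm(25 * 7), 25, 7)
  w <- matrix(rnorm(100 * 7), 100, 7)
  expect_identical(phenosom:::som_bmus(w, x_many),
                   vapply(seq_len(25), function(i) find_bmu(w, x_many[i, ]),
                          integer(1)))
})

test_that("batch cycle computes neighborhood buffer means", {
  # single node, nd = 0: plain mean
  gd1 <- matrix(0, 1, 1)
  w1 <- matrix(5, 1, 1)
  expect_equal(batch_cycle(w1, matrix(c(1, 3), 2, 1), 0, gd1),
               matrix(2, 1, 1), ignore_attr = TRUE)

  # constant data is a fixed point for every node with a nonempty buffer
  cfg <- som_config(3, 3, "rectangular", "link", init_jitter_sd = 0)
  gd <- grid_distances(cfg)
  w <- matrix(rnorm(9 * 2), 9, 2)
  v <- c(0.3, -0.7)
  x <- matrix(v, 10, 2, byrow = TRUE)
  w2 <- batch_cycle(w, x, 3, gd)  # radius covers the whole grid
  expect_true(all(abs(sweep(w2, 2, v)) < 1e-12))
})

test_that("2x2 grid batch cycle matches a hand-enumerated buffer oracle", {
  cfg <- som_config(2, 2, "rectangular", "link")
  gd <- grid_distances(cfg)
  # nodes at (1,1),(1,2),(2,1),(2,2); weights put each input on its own BMU
  w <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  x <- rbind(c(1, 1), c(9, -1), c(-1, 9), c(11, 11))
  # BMUs: input i -> node i. With nd = 1 each node's neighborhood is itself
  # plus orthogonal neighbors: node1 ~ {1,2,3}, node2 ~ {2,1,4},
  # node3 ~ {3,1,4}, node4 ~ {4,2,3}
  oracle <- rbind(colMeans(x[c(1, 2, 3), ]), colMeans(x[c(2, 1, 4), ]),
                  colMeans(x[c(3, 1, 4), ]), colMeans(x[c(4, 2, 3), ]))
  expect_equal(batch_cycle(w, x, 1, gd), oracle, ignore_attr = TRUE)
})

test_that("batch cycle at nd = 0 equals an independent Lloyd step", {
  set.seed(5)
  for (rep in 1:50) {
    n_nodes <- sample(3:8, 1)
    w <- matrix(rnorm(n_nodes * 3), n_nodes, 3)
    x <- matrix(rnorm(20 * 3), 20, 3)
    gd <- as.matrix(dist(matrix(seq_len(n_nodes))))  # any metric; nd = 0
    expect_equal(batch_cycle(w, x, 0, gd), lloyd_step(w, x),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("neighborhood schedule follows the linear ordering decay", {
  cfg <- som_config(initial_neighborhood = 3, ordering_steps = 5)
  expect_equal(neighborhood_schedule(cfg), c(3.4, 2.8, 2.2, 1.6, 1.0, 0))
  # the ordering phase always ends at exactly 1, for any INS
  for (ins in c(1, 2, 5, 10)) {
    s <- neighborhood_schedule(som_config(initial_neighborhood = ins))
    expect_equal(s[5], 1)
    expect_true(all(s[6:length(s)] < 1))  # fine-tuning below 1
  }
})

test_that("training on identical children collapses to a point", {
  x <- matrix(rep(c(1, -2, 0.5), each = 20), 20, 3)
  colnames(x) <- c("a", "b", "c")
  som <- suppressWarnings(train_som(x, som_config(4, 4, init_jitter_sd = 0)))
  expect_true(length(unique(som$bmu)) == 1)
  occupied <- unique(som$bmu)
  expect_true(all(abs(som$weights[occupied, ] - c(1, -2, 0.5)) < 1e-10))
})

test_that("well-separated clouds map to disjoint contiguous BMU regions", {
  set.seed(13)
  x <- rbind(matrix(rnorm(60 * 3, mean = 0), 60, 3),
             matrix(rnorm(60 * 3, mean = 6), 60, 3))
  colnames(x) <- c("a", "b", "c")
  cfg <- som_config(6, 6, init_jitter_sd = 0)
  som <- train_som(x, cfg)
  b1 <- unique(som$bmu[1:60]); b2 <- unique(som$bmu[61:120])
  expect_length(intersect(b1, b2), 0)
  # each cloud's BMU set is connected on the grid adjacency
  gd <- grid_distances(cfg)
  connected <- function(nodes) {
    if (length(nodes) == 1) return(TRUE)
    adj <- gd[nodes, nodes] <= 1 + 1e-6
    reach <- 1
    repeat {
      new <- unique(c(reach, which(colSums(adj[reach, , drop = FALSE]) > 0)))
      if (length(new) == length(reach)) break
      reach <- new
    }
    length(reach) == length(nodes)
  }
  expect_true(connected(b1))
  expect_true(connected(b2))
})

test_that("quantization error does not increase across ordering cycles", {
  for (s in 1:5) {
    gen <- generate_cohort(small_cohort_config(seed = s))
    som <- train_som(gen$cohort, fast_som_config(seed = s))
    qe <- som$quantization_error[seq_len(som$config$ordering_steps)]
    expect_true(all(diff(qe) <= 1e-9), info = paste("seed", s))
  }
})

test_that("similar children sit closer on the map than dissimilar ones", {
  # topographic ordering: mean grid distance between the most similar 5%
  # of child pairs is below that of the least similar 5%
  ratios <- vapply(1:10, function(s) {
    gen <- generate_cohort(small_cohort_config(seed = 30 + s))
    som <- train_som(gen$cohort, fast_som_config(seed = s))
    x <- cognitive_scores(gen$cohort)
    dx <- as.matrix(dist(x))
    coords <- bmu_coordinates(som)
    dg <- as.matrix(dist(coords))
    ut <- upper.tri(dx)
    qs <- quantile(dx[ut], c(0.05, 0.95))
    mean(dg[ut][dx[ut] <= qs[1]]) / mean(dg[ut][dx[ut] >= qs[2]])
  }, numeric(1))
  expect_true(all(ratios < 1))
})

test_that("training is fully deterministic given data, config and seed", {
  gen <- generate_cohort(small_cohort_config(seed = 2))
  a <- train_som(gen$cohort, fast_som_config(seed = 5))
  b <- train_som(gen$cohort, fast_som_config(seed = 5))
  expect_identical(a, b)
  c_ <- train_som(gen$cohort, fast_som_config(seed = 6))
  expect_false(identical(a$weights, c_$weights))
})

test_that("weight planes reshape the weight matrix and invert exactly", {
  gen <- generate_cohort(small_cohort_config(seed = 2))
  som <- train_som(gen$cohort, fast_som_config(seed = 5))
  planes <- weight_planes(som)
  expect_length(planes, ncol(som$weights))
  # plane value at node (r, c) is weights[node_index, measure]
  cfg <- som$config
  for (j in seq_along(planes)) {
    flat <- as.vector(t(planes[[j]]))   # row-major flatten
    expect_equal(flat, unname(som$weights[, j]))
  }
})

test_that("weight plane correlations behave on degenerate columns", {
  som <- list(weights = cbind(a = 1:10, b = 1:10, c = -(1:10)),
              config = som_config(5, 2))
  class(som) <- "trained_som"
  cc <- weight_plane_correlations(som)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  som$weights <- cbind(som$weights, d = rep(2, 10))
  expect_warning(cc2 <- weight_plane_correlations(som), "zero-variance")
  expect_true(is.na(cc2["a", "d"]))
})

test_that("shared cluster-mean profiles yield correlated weight planes", {
  # two measures with identical cluster-mean profiles but independent noise
  # correlate more strongly across the map than two with opposed profiles
  wins <- vapply(1:10, function(s) {
    means <- cbind(m1 = c(-1, 0, 1, 0), m2 = c(-1, 0, 1, 0),
                   m3 = c(1, 0, -1, 0))
    cfg <- cohort_config(cluster_sizes = c(40, 40, 40, 40),
                         cluster_means = means,
                         within_cluster_sd = 0.5,
                         within_cluster_corr = diag(3),
                         male_prob_per_cluster = rep(0.5, 4),
                         measure_families = rep("cognitive", 3),
                         category_rates = list(), seed = 50 + s)
    gen <- generate_scores(cfg)
    som <- train_som(gen$cohort, fast_som_config(seed = s))
    cc <- weight_plane_correlations(som)
    cc["m1", "m2"] > cc["m1", "m3"]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
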
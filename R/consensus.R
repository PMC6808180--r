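# k-means++ center selection (seeded by the caller's RNG state).
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' k-means clustering of SOM node weights
#'
#' Lloyd iterations with k-means++ seeding, best of \code{n_restarts}
#' restarts by total within-cluster sum of squares. Used to carve the
#' trained map into sections of similar node weights.
#'
#' @param weights Node x measure matrix.
#' @param k Number of clusters (2 <= k <= number of distinct weight rows,
#'   k = 1 is allowed and trivially groups all nodes).
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @return List with \code{labels} (per node), \code{centroids}
#'   (k x measure), and \code{tot_withinss}.
#' @export
cluster_nodes <- function(weights, k, seed = 1L, n_restarts = 10) {
  weights <- as.matrix(weights)
  if (k < 1 || k > nrow(weights)) stop("k must be in [1, number of nodes]")
  n_distinct <- nrow(unique(weights))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the number of distinct weight vectors (",
         n_distinct, ")")
  set.seed(seed)
  if (k == 1) {
    ctr <- matrix(colMeans(weights), 1)
    return(list(labels = rep(1L, nrow(weights)), centroids = ctr,
                tot_withinss = sum(sweep(weights, 2, ctr[1, ])^2)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_centers(weights, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(weights, centers = init,
                                     iter.max = 200, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  list(labels = as.integer(best$cluster),
       centroids = unname(best$centers),
       tot_withinss = best$tot.withinss)
}

#' Propagate node cluster labels to children
#'
#' A child belongs to the cluster of its best matching unit.
#'
#' @param node_labels Integer cluster label per node.
#' @param bmu Integer node index per child.
#' @return Integer cluster label per child.
#' @export
assign_children <- function(node_labels, bmu) {
  if (any(bmu < 1 | bmu > length(node_labels)))
    stop("bmu indexes a node without a label")
  node_labels[bmu]
}

# All permutations of 1..k (k <= 8 to keep enumeration cheap).
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Align cluster labels to a reference centroid set
#'
#' Finds the bijection between current and reference clusters minimizing the
#' total Euclidean distance between matched centroid pairs (exhaustive
#' search over the k! assignments; practical for the small k used here).
#'
#' @param reference_centroids,centroids k x measure matrices.
#' @return Integer vector \code{map} with \code{map[l]} = reference cluster
#'   matched to current cluster \code{l}; relabel with
#'   \code{map[labels]}.
#' @export
align_labels <- function(reference_centroids, centroids) {
  a <- as.matrix(reference_centroids)
  b <- as.matrix(centroids)
  if (!all(dim(a) == dim(b))) stop("centroid dimensions must match")
  k <- nrow(a)
  if (k > 8) stop("label alignment supports k <= 8")
  cost <- matrix(0, k, k)   # cost[i, l] = dist(reference i, current l)
  for (i in seq_len(k))
    cost[i, ] <- sqrt(rowSums(sweep(b, 2, a[i, ])^2))
  perms <- all_permutations(k)
  # perm row p: candidate map, current l -> reference perms[p, l]
  totals <- apply(perms, 1, function(pm) sum(cost[cbind(pm, seq_len(k))]))
  as.integer(perms[which.min(totals), ])
}

#' Consensus clustering over repeated map retrainings
#'
#' Repeats (retrain SOM with fresh jitter seed, k-means on the node weights,
#' align labels to the first iteration's centroids, record each child's
#' cluster) for \code{n_iterations} rounds, then assigns every child its
#' modal cluster, a consistency score (modal count / iterations), and a
#' chi-square clarity p-value against a uniform assignment profile.
#'
#' @param data A \code{cohort_matrix} (the SOM trains on its cognitive
#'   measures) or numeric matrix.
#' @param som_config A \code{som_config}; its \code{init_jitter_sd} should
#'   be positive so retrainings differ.
#' @param k Number of clusters (default 4).
#' @param n_iterations Number of retraining rounds (default 1000).
#' @param seed Master seed; per-iteration training and clustering seeds are
#'   derived from it.
#' @param vary_clustering If \code{FALSE}, reuse the first iteration's
#'   k-means seed on every iteration, so that with zero init jitter all
#'   iterations are identical (useful for determinism checks). Default
#'   \code{TRUE}.
#' @return An object of class \code{consensus_result} with
#'   \code{assignment_counts} (child x cluster), \code{modal_cluster},
#'   \code{consistency}, \code{clarity_p}, \code{reference_centroids},
#'   \code{reference_som}, \code{k}, and \code{n_iterations}.
#' @export
consensus <- function(data, som_config = som_config(), k = 4,
                      n_iterations = 1000, seed = 1L,
                      vary_clustering = TRUE) {
  x <- if (inherits(data, "cohort_matrix")) cognitive_scores(data) else as.matrix(data)
  n <- nrow(x)
  set.seed(seed)
  iter_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  2L * n_iterations), ncol = 2)
  counts <- matrix(0L, n, k)
  reference <- NULL
  ref_som <- NULL
  for (it in seq_len(n_iterations)) {
    cfg <- som_config
    cfg$seed <- iter_seeds[it, 1]
    som <- train_som(x, cfg)
    km_seed <- if (vary_clustering) iter_seeds[it, 2] else iter_seeds[1, 2]
    km <- cluster_nodes(som$weights, k, seed = km_seed)
    child_lab <- assign_children(km$labels, som$bmu)
    if (is.null(reference)) {
      reference <- km$centroids
      ref_som <- som
    } else {
      map <- align_labels(reference, km$centroids)
      child_lab <- map[child_lab]
    }
    counts[cbind(seq_len(n), child_lab)] <- counts[cbind(seq_len(n), child_lab)] + 1L
  }
  modal <- max.col(counts, ties.method = "first")
  consistency <- counts[cbind(seq_len(n), modal)] / n_iterations
  clarity <- apply(counts, 1, function(r) modal_clarity_test(r)$p_value)
  rownames(counts) <- rownames(x)
  structure(
    list(k = k, n_iterations = n_iterations,
         assignment_counts = counts,
         modal_cluster = stats::setNames(modal, rownames(x)),
         consistency = stats::setNames(consistency, rownames(x)),
         clarity_p = stats::setNames(clarity, rownames(x)),
         reference_centroids = reference,
         reference_som = ref_som,
         seed = seed),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: k =", x$k, "over", x$n_iterations, "iterations,",
      nrow(x$assignment_counts), "children\n")
  cat("  cluster sizes (modal):",
      paste(tabulate(x$modal_cluster, x$k), collapse = " / "), "\n")
  cat("  mean consistency:", signif(mean(x$consistency), 3),
      "| children with clarity p < 0.05:",
      sum(x$clarity_p < 0.05), "\n")
  invisible(x)
}

#' Chi-square clarity of a child's assignment profile
#'
#' Pearson goodness-of-fit of the per-cluster assignment counts against a
#' uniform expectation (iterations / k), on k - 1 degrees of freedom. A
#' small p-value means the child has a clear modal cluster rather than
#' bouncing evenly between clusters across retrainings.
#'
#' @param counts_row Integer vector of per-cluster assignment counts.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
modal_clarity_test <- function(counts_row) {
  k <- length(counts_row)
  n <- sum(counts_row)
  e <- n / k
  stat <- sum((counts_row - e)^2 / e)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

#' Per-cluster profile table
#'
#' Means and standard deviations of every measure by modal cluster, with
#' cluster sizes and (when labels are supplied) gender counts.
#'
#' @param data A \code{cohort_matrix}.
#' @param modal_cluster Integer cluster per child.
#' @param labels Optional label table with a \code{gender} column.
#' @return data.frame with one row per (cluster, measure) plus per-cluster
#'   \code{n} (and male/female counts when available).
#' @export
cluster_profile_table <- function(data, modal_cluster, labels = NULL) {
  x <- data$scores
  k <- max(modal_cluster)
  rows <- list()
  for (cl in seq_len(k)) {
    in_cl <- modal_cluster == cl
    n_cl <- sum(in_cl)
    for (j in seq_len(ncol(x))) {
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, measure = colnames(x)[j],
        family = data$measure_families[j], n = n_cl,
        mean = if (n_cl > 0) mean(x[in_cl, j]) else NA_real_,
        sd = if (n_cl > 1) stats::sd(x[in_cl, j]) else NA_real_,
        n_male = if (!is.null(labels)) sum(labels$gender[in_cl] == "male") else NA_integer_,
        n_female = if (!is.null(labels)) sum(labels$gender[in_cl] == "female") else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
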
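#' Default measure table for a struggling-learner cohort
#'
#' The seven cognitive measures used for map training plus the three learning
#' outcomes, each tagged with its measure family. The cognitive battery covers
#' fluid reasoning, vocabulary, phonological awareness, and verbal/spatial
#' short-term and working memory; the learning outcomes are spelling, reading,
#' and maths, all expressed as z-scores against age-matched norms.
#'
#' @return A data.frame with columns \code{name} and
#'   \code{family} (\code{"cognitive"} or \code{"learning"}).
#' @export
default_measures <- function() {
  data.frame(
    name = c("matrix_reasoning", "vocabulary", "phon_awareness",
             "verbal_stm", "spatial_stm", "verbal_wm", "spatial_wm",
             "spelling", "reading", "maths"),
    family = c(rep("cognitive", 7), rep("learning", 3)),
    stringsAsFactors = FALSE
  )
}

# Cluster-by-measure mean z-scores for the four generating profiles:
# broad deficits, working-memory deficits, age-appropriate, phonological
# deficits. Rows are clusters, columns follow default_measures().
default_cluster_means <- function() {
  m <- rbind(
    c(-1.42, -1.10, -1.17, -1.44, -1.24, -1.41, -0.87, -1.58, -1.60, -1.77),
    c(-0.71,  0.08, -0.41, -0.19, -1.12, -0.55, -0.45, -1.05, -0.90, -1.02),
    c( 0.04,  0.87, -0.17,  0.44,  0.29,  0.18,  0.45, -0.47,  0.02, -0.32),
    c(-0.63, -0.47, -0.91, -0.79, -0.11, -0.66,  0.23, -1.17, -1.09, -1.13)
  )
  dimnames(m) <- list(paste0("cluster", 1:4), default_measures()$name)
  m
}

# Per-cluster category membership probabilities, chosen so expected counts
# match a reference cohort of 146/121/132/131 children.
default_category_rates <- function() {
  sizes <- c(146, 121, 132, 131)
  list(
    referral = rbind(
      attention   = c(36, 48, 52, 39) / sizes,
      memory      = c(16, 11, 12, 16) / sizes,
      language    = c(25,  7, 12, 15) / sizes,
      poor_school = c(67, 51, 51, 58) / sizes
    ),
    diagnosis = rbind(
      adhd     = c(29, 35, 22, 28) / sizes,
      slt      = c(43, 16, 15, 24) / sizes,
      dyslexia = c(11,  9,  5,  5) / sizes,
      asd      = c( 9,  6, 11,  6) / sizes,
      sus_adhd = c(15, 14, 18, 10) / sizes
    )
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates everything the generator needs: cluster sizes and
#' mean profiles, the within-cluster noise model (per-measure standard
#' deviations and a common correlation matrix), per-cluster categorical
#' rates, and a seed. Defaults emulate a referred cohort of 530 children in
#' four cognitive-profile clusters. The within-cluster dispersion and
#' inter-measure correlation are not identified by group-level summaries, so
#' the defaults (sd 0.5, exchangeable correlation 0.3) are stand-ins chosen
#' to make clusters overlap at their boundaries yet remain recoverable.
#'
#' @param cluster_sizes Positive integers; children per generating cluster.
#' @param cluster_means Cluster-by-measure matrix of z-score means.
#' @param within_cluster_sd Per-measure positive standard deviation (recycled
#'   if scalar).
#' @param within_cluster_corr Measure-by-measure correlation matrix; must be
#'   symmetric positive semi-definite with unit diagonal.
#' @param category_rates List of per-category rate matrices
#'   (category x cluster), probabilities in \[0, 1\].
#' @param male_prob_per_cluster Probability of male per cluster.
#' @param age_range_months Integer interval for uniform age draws.
#' @param measure_families Family tag per measure.
#' @param seed Integer seed; makes all generation deterministic.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(cluster_sizes = c(146, 121, 132, 131),
                          cluster_means = default_cluster_means(),
                          within_cluster_sd = 0.5,
                          within_cluster_corr = NULL,
                          category_rates = default_category_rates(),
                          male_prob_per_cluster = c(87, 83, 105, 91) /
                            c(146, 121, 132, 131),
                          age_range_months = c(65L, 215L),
                          measure_families = default_measures()$family,
                          seed = 1L) {
  cluster_means <- as.matrix(cluster_means)
  n_clusters <- length(cluster_sizes)
  n_measures <- ncol(cluster_means)
  if (any(cluster_sizes < 1) || any(cluster_sizes != round(cluster_sizes)))
    stop("cluster_sizes must be positive integers")
  if (nrow(cluster_means) != n_clusters)
    stop("cluster_means must have one row per cluster")
  sds <- rep_len(within_cluster_sd, n_measures)
  if (any(sds < 0)) stop("within_cluster_sd must be nonnegative")
  if (is.null(within_cluster_corr)) {
    within_cluster_corr <- matrix(0.3, n_measures, n_measures)
    diag(within_cluster_corr) <- 1
  }
  within_cluster_corr <- as.matrix(within_cluster_corr)
  if (!isTRUE(all.equal(within_cluster_corr, t(within_cluster_corr))) ||
      any(abs(diag(within_cluster_corr) - 1) > 1e-8))
    stop("within_cluster_corr must be symmetric with unit diagonal")
  ev <- eigen(within_cluster_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("within_cluster_corr is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")
  for (nm in names(category_rates)) {
    r <- category_rates[[nm]]
    if (any(r < 0 | r > 1))
      stop("category_rates$", nm, " has probabilities outside [0, 1]")
  }
  if (any(male_prob_per_cluster < 0 | male_prob_per_cluster > 1))
    stop("male_prob_per_cluster must lie in [0, 1]")
  if (length(measure_families) != n_measures)
    stop("measure_families must match the number of measures")
  if (is.null(colnames(cluster_means)))
    colnames(cluster_means) <- paste0("measure", seq_len(n_measures))
  structure(
    list(cluster_sizes = as.integer(cluster_sizes),
         cluster_means = cluster_means,
         within_cluster_sd = sds,
         within_cluster_corr = within_cluster_corr,
         category_rates = category_rates,
         male_prob_per_cluster = male_prob_per_cluster,
         age_range_months = as.integer(age_range_months),
         measure_families = measure_families,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Construct a cohort matrix
#'
#' Container for a children-by-measures z-score matrix with measure family
#' metadata. Cognitive measures must be complete for every included child.
#'
#' @param scores Numeric matrix, children x measures, with column names.
#' @param child_ids Unique child identifiers (default taken from rownames).
#' @param measure_families Family tag per measure
#'   (\code{cognitive}/\code{learning}/\code{behavior}).
#' @return An object of class \code{cohort_matrix}.
#' @export
cohort_matrix <- function(scores, child_ids = rownames(scores),
                          measure_families = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have measure column names")
  if (anyDuplicated(colnames(scores))) stop("measure names must be unique")
  if (is.null(child_ids)) child_ids <- sprintf("child_%04d", seq_len(nrow(scores)))
  if (anyDuplicated(child_ids)) stop("child_ids must be unique")
  if (is.null(measure_families))
    measure_families <- rep("cognitive", ncol(scores))
  cog <- scores[, measure_families == "cognitive", drop = FALSE]
  if (anyNA(cog))
    stop("cognitive measures must be complete for all included children")
  rownames(scores) <- child_ids
  structure(list(scores = scores,
                 child_ids = child_ids,
                 measure_families = measure_families),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", nrow(x$scores), "children x", ncol(x$scores),
      "measures\n")
  cat("  families:", paste(sprintf("%s (%d)",
                                   names(table(x$measure_families)),
                                   table(x$measure_families)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Extract the cognitive score block of a cohort
#'
#' @param cohort A \code{cohort_matrix}.
#' @return Numeric matrix restricted to measures tagged \code{cognitive}.
#' @export
cognitive_scores <- function(cohort) {
  cohort$scores[, cohort$measure_families == "cognitive", drop = FALSE]
}

#' Generate synthetic cohort scores
#'
#' Draws each child's score row from a multivariate normal with its
#' generating cluster's mean vector and common covariance
#' \code{diag(sd) \%*\% corr \%*\% diag(sd)}. Output is deterministic given
#' the config seed.
#'
#' @param config A \code{cohort_config}.
#' @return A list with \code{cohort} (a \code{cohort_matrix}) and
#'   \code{labels} (data.frame with \code{child_id} and
#'   \code{generating_cluster}).
#' @export
generate_scores <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_total <- sum(config$cluster_sizes)
  n_measures <- ncol(config$cluster_means)
  sigma <- diag(config$within_cluster_sd) %*% config$within_cluster_corr %*%
    diag(config$within_cluster_sd)
  scores <- matrix(NA_real_, n_total, n_measures,
                   dimnames = list(NULL, colnames(config$cluster_means)))
  gen_cluster <- rep(seq_along(config$cluster_sizes), config$cluster_sizes)
  row0 <- 0L
  for (c_idx in seq_along(config$cluster_sizes)) {
    n_c <- config$cluster_sizes[c_idx]
    draw <- MASS::mvrnorm(n_c, mu = config$cluster_means[c_idx, ],
                          Sigma = sigma)
    scores[row0 + seq_len(n_c), ] <- draw
    row0 <- row0 + n_c
  }
  ids <- sprintf("child_%04d", seq_len(n_total))
  list(
    cohort = cohort_matrix(scores, ids, config$measure_families),
    labels = data.frame(child_id = ids, generating_cluster = gen_cluster,
                        stringsAsFactors = FALSE)
  )
}

#' Generate categorical labels for a synthetic cohort
#'
#' Draws gender, age, referral reason, and diagnosis flags for each child,
#' independently given the child's generating cluster: gender is Bernoulli
#' with the cluster's male probability, age uniform on the configured range,
#' referral a single draw among the referral categories (with a residual
#' \code{none} probability), and each diagnosis flag an independent Bernoulli
#' at the cluster's rate.
#'
#' @param labels Label table containing \code{generating_cluster}.
#' @param config A \code{cohort_config}.
#' @return The label table extended with \code{gender}, \code{age_months},
#'   \code{referral_reason}, and one logical column per diagnosis.
#' @export
generate_categories <- function(labels, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(labels$generating_cluster))
    stop("labels must contain generating_cluster")
  set.seed(config$seed + 1L)
  cl <- labels$generating_cluster
  n <- nrow(labels)

  labels$gender <- ifelse(
    stats::runif(n) < config$male_prob_per_cluster[cl], "male", "female")
  labels$age_months <- sample(
    seq(config$age_range_months[1], config$age_range_months[2]),
    n, replace = TRUE)

  ref_rates <- config$category_rates$referral     # category x cluster
  p_none <- pmax(0, 1 - colSums(ref_rates))
  ref_levels <- c(rownames(ref_rates), "none")
  labels$referral_reason <- vapply(seq_len(n), function(i) {
    probs <- c(ref_rates[, cl[i]], p_none[cl[i]])
    sample(ref_levels, 1L, prob = probs)
  }, character(1))

  diag_rates <- config$category_rates$diagnosis
  for (d in rownames(diag_rates)) {
    labels[[d]] <- stats::runif(n) < diag_rates[d, cl]
  }
  labels
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running \code{\link{generate_scores}} then
#' \code{\link{generate_categories}}.
#'
#' @param config A \code{cohort_config}.
#' @return List with \code{cohort} and fully populated \code{labels}.
#' @export
generate_cohort <- function(config = cohort_config()) {
  out <- generate_scores(config)
  out$labels <- generate_categories(out$labels, config)
  out
}

#' Generate synthetic streamline-count connectomes
#'
#' Produces one symmetric nonnegative weighted matrix per child in each
#' group. Every off-diagonal edge weight is drawn independently as
#' \code{N(base_weight, noise_sd)} (clamped at zero), except that in groups
#' named in \code{deficit_groups} all edges incident to
#' \code{deficit_regions} have their mean reduced by \code{deficit_delta} --
#' a planted regional deficit for power studies of the two-stage regional
#' comparison.
#'
#' @param n_per_group Named vector of children per group.
#' @param n_rois Number of regions (>= 2).
#' @param base_weight Mean edge weight.
#' @param deficit_regions Integer ROI indices carrying the deficit.
#' @param deficit_delta Mean reduction on deficit-incident edges; must not
#'   drive the mean weight negative.
#' @param deficit_groups Names (or indices) of the groups carrying the
#'   deficit; defaults to none.
#' @param noise_sd Edge-weight standard deviation.
#' @param seed Integer seed.
#' @return Named list (one element per group) of lists of symmetric
#'   \code{n_rois x n_rois} matrices with zero diagonal.
#' @export
generate_connectomes <- function(n_per_group, n_rois = 85,
                                 base_weight = 1, deficit_regions = integer(0),
                                 deficit_delta = 0, deficit_groups = character(0),
                                 noise_sd = 0.1, seed = 1L) {
  if (n_rois < 2) stop("n_rois must be >= 2")
  if (length(deficit_regions) &&
      (min(deficit_regions) < 1 || max(deficit_regions) > n_rois))
    stop("deficit_regions must index ROIs in [1, n_rois]")
  if (base_weight - deficit_delta < 0)
    stop("deficit_delta ", deficit_delta,
         " would make mean edge weights negative (base_weight ",
         base_weight, ")")
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  if (is.numeric(deficit_groups)) deficit_groups <- names(n_per_group)[deficit_groups]

  set.seed(seed)
  ut <- upper.tri(matrix(0, n_rois, n_rois))
  mean_mat_base <- matrix(base_weight, n_rois, n_rois)
  mean_mat_def <- mean_mat_base
  if (length(deficit_regions)) {
    incident <- matrix(FALSE, n_rois, n_rois)
    incident[deficit_regions, ] <- TRUE
    incident[, deficit_regions] <- TRUE
    mean_mat_def[incident] <- base_weight - deficit_delta
  }
  lapply(stats::setNames(names(n_per_group), names(n_per_group)), function(g) {
    mu <- if (g %in% deficit_groups) mean_mat_def else mean_mat_base
    lapply(seq_len(n_per_group[[g]]), function(i) {
      m <- matrix(0, n_rois, n_rois)
      m[ut] <- pmax(0, stats::rnorm(sum(ut), mean = mu[ut], sd = noise_sd))
      m <- m + t(m)
      m
    })
  })
}
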
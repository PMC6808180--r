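#' One-way fixed-effects ANOVA
#'
#' Classical F test of equal group means, df = (g - 1, N - g).
#'
#' @param values Numeric vector.
#' @param group_labels Group label per value (>= 2 groups with >= 2
#'   observations each).
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p_value}.
#'   When the within-group variance is zero and group means are equal the F
#'   statistic is undefined and reported as \code{NA}.
#' @export
oneway_anova <- function(values, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  f <- unname(fit$statistic)
  if (!is.finite(f)) {
    means <- tapply(values, g, mean)
    if (max(means) - min(means) < 1e-12) f <- NA_real_
  }
  list(F = f, df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       p_value = unname(fit$p.value))
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group comparisons with studentized-range adjusted p-values,
#' using Tukey-Kramer standard errors for unequal group sizes (via
#' \code{\link[stats]{TukeyHSD}}).
#'
#' @param values Numeric vector.
#' @param group_labels Group label per value.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return data.frame with one row per unordered group pair: \code{pair},
#'   \code{diff}, \code{lwr}, \code{upr}, \code{p_adj}. Pairs involving a
#'   singleton group carry \code{NA} (untestable).
#' @export
tukey_posthoc <- function(values, group_labels, conf_level = 0.95) {
  g <- factor(group_labels)
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  singletons <- names(table(g))[table(g) < 2]
  if (length(singletons)) {
    hit <- vapply(strsplit(out$pair, "-", fixed = TRUE),
                  function(p) any(p %in% singletons), logical(1))
    out$p_adj[hit] <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Chi-square test of category membership distribution across clusters
#'
#' One-way Pearson goodness-of-fit of the member counts across clusters,
#' with expected counts proportional to cluster sizes
#' (\code{E_c = total_members * n_c / N}), on (#clusters - 1) degrees of
#' freedom. Tests whether category members are over- or under-represented
#' in particular clusters relative to cluster size.
#'
#' @param member_counts Members per cluster (nonnegative integers).
#' @param cluster_sizes Children per cluster.
#' @param category Optional category name carried into the result.
#' @return List with \code{category}, \code{observed}, \code{expected},
#'   \code{chi2}, \code{df}, \code{p_value}.
#' @export
category_distribution_chi2 <- function(member_counts, cluster_sizes,
                                       category = NA_character_) {
  if (length(member_counts) != length(cluster_sizes))
    stop("member_counts and cluster_sizes must align")
  if (any(member_counts < 0) || any(member_counts > cluster_sizes))
    stop("member_counts must lie in [0, cluster_sizes]")
  total <- sum(member_counts)
  if (total < 1) stop("need at least one member")
  e <- total * cluster_sizes / sum(cluster_sizes)
  if (any(e == 0)) stop("zero expected count (empty cluster)")
  chi2 <- sum((member_counts - e)^2 / e)
  df <- length(member_counts) - 1L
  list(category = category, observed = member_counts, expected = e,
       chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Gender goodness-of-fit for one cluster
#'
#' 1-df chi-square of a cluster's male/female counts against expectations
#' from the overall sample's male proportion, without continuity
#' correction. Detects clusters with a disproportionate gender balance.
#'
#' @param cluster_mf Integer vector \code{c(males, females)} in the cluster.
#' @param overall_mf Integer vector \code{c(males, females)} in the full
#'   sample.
#' @return List with \code{chi2}, \code{df}, \code{p_value},
#'   \code{expected}.
#' @export
gender_gof_chi2 <- function(cluster_mf, overall_mf) {
  if (any(overall_mf <= 0)) stop("overall counts must be positive")
  p_male <- overall_mf[1] / sum(overall_mf)
  n <- sum(cluster_mf)
  e <- c(n * p_male, n * (1 - p_male))
  if (any(e == 0)) stop("zero expected count")
  chi2 <- sum((cluster_mf - e)^2 / e)
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
       expected = e)
}

#' Bonferroni correction within measure families
#'
#' Each p-value is multiplied by the number of tests in its own family
#' (cognitive, learning, behavior, ...) and capped at 1, so correction
#' severity matches the number of comparisons actually made within a data
#' type.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param family Family label per p-value (defaults to one family).
#' @return Corrected p-values, same order as the input.
#' @export
bonferroni_by_family <- function(p_values, family = rep("all", length(p_values))) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- stats::ave(p_values, family, FUN = length)
  pmin(1, p_values * m)
}

#' Compare cluster profiles on every measure
#'
#' Runs a one-way ANOVA of each measure across modal clusters, corrects
#' p-values by Bonferroni within each measure family, and attaches Tukey
#' post hoc tables.
#'
#' @param data A \code{cohort_matrix}.
#' @param modal_cluster Integer cluster per child.
#' @return List with \code{tests} (data.frame: measure, family, F, df1,
#'   df2, p_raw, p_corrected) and \code{pairwise} (named list of Tukey
#'   tables).
#' @export
compare_cluster_profiles <- function(data, modal_cluster) {
  x <- data$scores
  res <- lapply(seq_len(ncol(x)), function(j) {
    keep <- !is.na(x[, j])
    a <- oneway_anova(x[keep, j], modal_cluster[keep])
    data.frame(measure = colnames(x)[j], family = data$measure_families[j],
               F = a$F, df1 = a$df1, df2 = a$df2, p_raw = a$p_value,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, res)
  tests$p_corrected <- bonferroni_by_family(tests$p_raw, tests$family)
  pairwise <- lapply(stats::setNames(seq_len(ncol(x)), colnames(x)),
                     function(j) {
                       keep <- !is.na(x[, j])
                       tukey_posthoc(x[keep, j], modal_cluster[keep])
                     })
  list(tests = tests, pairwise = pairwise)
}

# Varimax from multiple orthonormal starting rotations, keeping the
# solution with the highest (Kaiser-normalized) criterion: the iterative
# rotation can stall in a local optimum from the identity start.
varimax_multistart <- function(load_raw, n_starts = 10) {
  k <- ncol(load_raw)
  comm <- sqrt(rowSums(load_raw^2))
  crit <- function(m) sum(apply((m / comm)^2, 2, stats::var))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(760423L)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) diag(k) else qr.Q(qr(matrix(stats::rnorm(k * k), k)))
    cand <- unclass(stats::varimax(load_raw %*% start, eps = 1e-8)$loadings)
    if (is.null(best) || crit(cand) > crit(best)) best <- cand
  }
  best
}

#' Rotated principal-component factors for questionnaire subscales
#'
#' PCA on the subscale correlation matrix, retaining \code{n_factors}
#' components, varimax rotation, and per-child factor scores by the
#' regression method, standardized to mean 0 / sd 1. Reduces a
#' questionnaire's subscales to a small number of interpretable factors
#' before group comparison.
#'
#' @param subscale_matrix Numeric child x subscale matrix; rows with any
#'   missing value are dropped.
#' @param n_factors Number of factors to retain (default 2).
#' @return List with \code{loadings} (subscale x factor, rotated),
#'   \code{scores} (child x factor, standardized), \code{variance_explained}
#'   (percent, per retained factor), \code{total_variance_explained}
#'   (percent), \code{rotation}, and \code{kept_rows} (logical, which input
#'   rows had complete data).
#' @export
questionnaire_factors <- function(subscale_matrix, n_factors = 2) {
  x <- as.matrix(subscale_matrix)
  if (ncol(x) < n_factors) stop("need at least n_factors subscales")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant subscale(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  eg <- eigen(r, symmetric = TRUE)
  lam <- eg$values[seq_len(n_factors)]
  load_raw <- eg$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(lam), n_factors)
  loadings <- varimax_multistart(load_raw)
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("factor", seq_len(n_factors))
  # regression-method scores on standardized subscales; the generalized
  # inverse covers rank-deficient correlation matrices (noise-free data)
  z <- scale(x)
  coefs <- MASS::ginv(r) %*% loadings
  scores <- z %*% coefs
  scores <- scale(scores)
  colnames(scores) <- colnames(loadings)
  var_exp <- colSums(loadings^2) / ncol(x) * 100
  list(loadings = loadings, scores = scores,
       variance_explained = var_exp,
       total_variance_explained = sum(var_exp),
       rotation = "varimax", kept_rows = keep)
}
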
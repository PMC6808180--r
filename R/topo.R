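#' Two-sample two-dimensional Kolmogorov-Smirnov statistic
#'
#' For each candidate origin and each of the four quadrant orientations
#' ({x <= x0 or x > x0} x {y <= y0 or y > y0}), compare the fraction of each
#' sample falling in the quadrant; D is the maximum absolute difference.
#' Candidate origins are all combinations of observed x and observed y
#' coordinate values, which on a discrete grid attains the same maximum as
#' scanning every grid point. Points form a multiset: children sharing a
#' node contribute multiplicity.
#'
#' @param points_a,points_b Two-column matrices of 2D coordinates (nonempty).
#' @return D in \[0, 1\].
#' @export
ks2d_statistic <- function(points_a, points_b) {
  a <- matrix(as.numeric(points_a), ncol = 2)
  b <- matrix(as.numeric(points_b), ncol = 2)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both samples must be nonempty")
  ux <- sort(unique(c(a[, 1], b[, 1])))
  uy <- sort(unique(c(a[, 2], b[, 2])))
  quad_fracs <- function(p) {
    n <- nrow(p)
    xle <- outer(ux, p[, 1], ">=") * 1          # origins_x x points
    yle <- outer(uy, p[, 2], ">=") * 1
    n11 <- xle %*% t(yle)                       # x <= x0 & y <= y0
    rx <- rowSums(xle)
    ry <- rowSums(yle)
    n12 <- outer(rx, rep(1, length(uy))) - n11  # x <= x0 & y > y0
    n21 <- outer(rep(1, length(ux)), ry) - n11  # x > x0 & y <= y0
    n22 <- n - n11 - n12 - n21
    list(n11 / n, n12 / n, n21 / n, n22 / n)
  }
  fa <- quad_fracs(a)
  fb <- quad_fracs(b)
  max(vapply(1:4, function(q) max(abs(fa[[q]] - fb[[q]])), numeric(1)))
}

#' Permutation test for topographic distribution differences
#'
#' Tests whether the map positions of a category's members are drawn from
#' the same 2D distribution as those of nonmembers, using the two-sample 2D
#' KS statistic with significance from random relabeling of membership:
#' p = (1 + #\{D_perm >= D_obs\}) / (1 + n_permutations).
#'
#' @param coords Per-child 2D coordinates (children x 2), typically
#'   \code{\link{bmu_coordinates}} output.
#' @param membership Logical vector, one entry per child; must contain at
#'   least 2 members and 2 nonmembers.
#' @param n_permutations Number of label shuffles (default 9999).
#' @param seed Integer seed.
#' @param category_name Label carried into the result.
#' @return An object of class \code{topo_test} with fields
#'   \code{category_name}, \code{D}, \code{p_value}, \code{n_members},
#'   \code{n_nonmembers}, \code{n_permutations}, \code{seed}.
#' @export
ks2d_permutation_test <- function(coords, membership, n_permutations = 9999,
                                  seed = 1L, category_name = "category") {
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 2)
  membership <- as.logical(membership)
  if (length(membership) != nrow(coords))
    stop("membership length must match number of coordinate rows")
  n_m <- sum(membership)
  n_nm <- sum(!membership)
  if (n_m < 2 || n_nm < 2)
    stop("need at least 2 members and 2 nonmembers (got ", n_m, " / ", n_nm, ")")
  d_obs <- ks2d_statistic(coords[membership, , drop = FALSE],
                          coords[!membership, , drop = FALSE])
  set.seed(seed)
  n_ge <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample(membership)
    d_p <- ks2d_statistic(coords[perm, , drop = FALSE],
                          coords[!perm, , drop = FALSE])
    if (d_p >= d_obs - 1e-12) n_ge <- n_ge + 1L
  }
  structure(
    list(category_name = category_name, D = d_obs,
         p_value = (1 + n_ge) / (1 + n_permutations),
         n_members = n_m, n_nonmembers = n_nm,
         n_permutations = n_permutations, seed = seed),
    class = "topo_test"
  )
}

#' @export
print.topo_test <- function(x, ...) {
  cat(sprintf("topo_test '%s': D = %.4f, p = %.4g (%d members vs %d nonmembers, %d permutations)\n",
              x$category_name, x$D, x$p_value, x$n_members, x$n_nonmembers,
              x$n_permutations))
  invisible(x)
}

#' Split BMU coordinates by category membership
#'
#' Resolves a category against the label table -- either a logical column
#' (diagnosis flags) or a value of \code{referral_reason} -- and splits the
#' children's BMU grid coordinates into member and nonmember sets.
#'
#' @param som A \code{trained_som} whose children match \code{labels} rows.
#' @param labels Label table (one row per child, in training order).
#' @param category Name of a logical label column, or a referral-reason
#'   value.
#' @return List with \code{member_coords}, \code{nonmember_coords},
#'   \code{membership}, and counts.
#' @export
category_topography <- function(som, labels, category) {
  if (length(som$bmu) != nrow(labels))
    stop("labels must have one row per mapped child")
  if (category %in% names(labels) && is.logical(labels[[category]])) {
    membership <- labels[[category]]
  } else if (!is.null(labels$referral_reason) &&
             category %in% labels$referral_reason) {
    membership <- labels$referral_reason == category
  } else {
    stop("unknown category '", category, "'")
  }
  coords <- bmu_coordinates(som)
  list(member_coords = coords[membership, , drop = FALSE],
       nonmember_coords = coords[!membership, , drop = FALSE],
       membership = membership,
       n_members = sum(membership),
       n_nonmembers = sum(!membership))
}

#' Run topographic tests for a set of categories
#'
#' Convenience wrapper: for each category, split BMUs by membership and run
#' the 2D KS permutation test. No multiple-comparison correction is applied
#' by default; set \code{correction = "bonferroni"} to correct across the
#' tested categories.
#'
#' @param som A \code{trained_som}.
#' @param labels Label table aligned with the training data.
#' @param categories Character vector of categories (see
#'   \code{\link{category_topography}}).
#' @param n_permutations,seed Passed to \code{\link{ks2d_permutation_test}}.
#' @param correction \code{"none"} (default) or \code{"bonferroni"}.
#' @return data.frame with one row per category: n_members, D, p_raw,
#'   p_corrected, n_permutations, seed.
#' @export
topography_tests <- function(som, labels, categories,
                             n_permutations = 9999, seed = 1L,
                             correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  rows <- lapply(seq_along(categories), function(i) {
    ct <- category_topography(som, labels, categories[i])
    tt <- ks2d_permutation_test(bmu_coordinates(som), ct$membership,
                                n_permutations = n_permutations,
                                seed = seed + i - 1L,
                                category_name = categories[i])
    data.frame(category = categories[i], n_members = tt$n_members,
               D = tt$D, p_raw = tt$p_value,
               n_permutations = n_permutations, seed = tt$seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- if (correction == "bonferroni")
    pmin(1, out$p_raw * nrow(out)) else out$p_raw
  out[, c("category", "n_members", "D", "p_raw", "p_corrected",
          "n_permutations", "seed")]
}
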
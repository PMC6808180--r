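#' Build a weighted connectome from streamline counts
#'
#' Symmetrizes the count matrix by averaging it with its transpose (the
#' symmetric intersection of streamlines seeded from either region) and
#' applies the log10(1 + count) transform, so that zero streamlines map to
#' weight zero and the transform stays defined everywhere. The diagonal is
#' zeroed.
#'
#' @param count_matrix Square nonnegative matrix of streamline counts.
#' @param roi_names Optional ROI names (applied to both dimensions).
#' @return Symmetric nonnegative weight matrix with zero diagonal.
#' @export
weight_from_counts <- function(count_matrix, roi_names = NULL) {
  m <- as.matrix(count_matrix)
  if (nrow(m) != ncol(m)) stop("count matrix must be square")
  if (any(m < 0)) stop("streamline counts must be nonnegative")
  w <- log10(1 + (m + t(m)) / 2)
  diag(w) <- 0
  if (!is.null(roi_names)) dimnames(w) <- list(roi_names, roi_names)
  w
}

#' Regional connection strength
#'
#' The sum of all connection weights per region (node strength).
#'
#' @param weights Symmetric ROI x ROI weight matrix, or a list of such
#'   matrices (one per child).
#' @return Numeric vector of per-ROI strengths, or a children x ROI matrix
#'   for a list input.
#' @export
regional_strength <- function(weights) {
  if (is.list(weights)) {
    out <- t(vapply(weights, rowSums, numeric(nrow(weights[[1]]))))
    rownames(out) <- names(weights)
    return(out)
  }
  rowSums(weights)
}

# Vectorized two-sample Welch t per column of two matrices.
welch_t_cols <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Two-stage regional group comparison
#'
#' Stage 1 screens every region with an uncorrected two-sample Welch t-test
#' of the deficit group against the within-sample reference group
#' (p < \code{alpha1}). Stage 2 retests only the screened regions against
#' an external comparison group, controlling the false discovery rate by
#' Benjamini-Hochberg at level \code{q} within the screened set. A region
#' is selected only if it passes both stages.
#'
#' @param deficit_group,reference_group,external_group Children x ROI
#'   matrices of regional strengths (>= 2 children each).
#' @param alpha1 Stage-1 screening level (default 0.05, uncorrected).
#' @param q Stage-2 FDR level (default 0.05).
#' @param roi_names Optional ROI names.
#' @return data.frame with one row per ROI: \code{roi}, \code{stage1_t},
#'   \code{stage1_p}, \code{screened}, \code{stage2_t}, \code{stage2_p},
#'   \code{stage2_p_fdr}, \code{selected}. Stage-2 columns are \code{NA}
#'   for unscreened regions.
#' @export
two_stage_region_test <- function(deficit_group, reference_group,
                                  external_group, alpha1 = 0.05, q = 0.05,
                                  roi_names = NULL) {
  d <- as.matrix(deficit_group)
  r <- as.matrix(reference_group)
  e <- as.matrix(external_group)
  if (nrow(d) < 2 || nrow(r) < 2 || nrow(e) < 2)
    stop("every group needs at least 2 children")
  if (ncol(d) != ncol(r) || ncol(d) != ncol(e))
    stop("groups must share the same ROI set")
  n_roi <- ncol(d)
  if (is.null(roi_names))
    roi_names <- colnames(d) %||% paste0("roi", seq_len(n_roi))
  s1 <- welch_t_cols(d, r)
  screened <- s1$p < alpha1
  out <- data.frame(roi = roi_names, stage1_t = s1$t, stage1_p = s1$p,
                    screened = screened,
                    stage2_t = NA_real_, stage2_p = NA_real_,
                    stage2_p_fdr = NA_real_, selected = FALSE,
                    stringsAsFactors = FALSE)
  if (any(screened)) {
    s2 <- welch_t_cols(d[, screened, drop = FALSE], e[, screened, drop = FALSE])
    out$stage2_t[screened] <- s2$t
    out$stage2_p[screened] <- s2$p
    out$stage2_p_fdr[screened] <- stats::p.adjust(s2$p, method = "BH")
    out$selected <- out$screened & !is.na(out$stage2_p_fdr) &
      out$stage2_p_fdr < q
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lobe-level nonparametric group comparison
#'
#' Summarizes each child's regional strengths to one score per lobe (the
#' mean strength over that lobe's ROIs), then compares the two groups per
#' lobe with a two-sided Mann-Whitney U test (U reported as the smaller of
#' U1 and U2; exact enumeration below a combined n of 20, normal
#' approximation with tie correction otherwise), reporting group medians
#' and median absolute deviations, with Benjamini-Hochberg correction
#' across the lobes.
#'
#' @param strengths_a,strengths_b Children x ROI strength matrices for the
#'   two groups.
#' @param lobe_map Character vector, one lobe per ROI (every ROI must be
#'   mapped).
#' @return data.frame with one row per lobe: medians and MADs per group,
#'   \code{U}, \code{p_raw}, \code{p_fdr}.
#' @export
lobe_comparison <- function(strengths_a, strengths_b, lobe_map) {
  a <- as.matrix(strengths_a)
  b <- as.matrix(strengths_b)
  if (length(lobe_map) != ncol(a) || ncol(a) != ncol(b))
    stop("lobe_map must name a lobe for every ROI")
  if (anyNA(lobe_map)) {
    bad <- which(is.na(lobe_map))
    stop("unmapped ROI(s): ", paste(colnames(a)[bad] %||% bad, collapse = ", "))
  }
  lobes <- unique(lobe_map)
  rows <- lapply(lobes, function(lb) {
    cols <- lobe_map == lb
    sa <- rowMeans(a[, cols, drop = FALSE])
    sb <- rowMeans(b[, cols, drop = FALSE])
    exact <- (length(sa) + length(sb)) < 20
    wt <- suppressWarnings(
      stats::wilcox.test(sa, sb, exact = exact, correct = TRUE))
    u1 <- unname(wt$statistic)
    u <- min(u1, length(sa) * length(sb) - u1)
    data.frame(lobe = lb,
               median_a = stats::median(sa), mad_a = stats::mad(sa, constant = 1),
               median_b = stats::median(sb), mad_b = stats::mad(sb, constant = 1),
               U = u, p_raw = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Default lobe assignment for a Desikan-Killiany style parcellation
#'
#' A synthetic stand-in mapping for simulation work: splits \code{n_rois}
#' regions into five lobes (frontal, temporal, parietal, occipital,
#' subcortical) in fixed proportion. Real analyses should supply their own
#' parcellation-derived map.
#'
#' @param n_rois Number of regions.
#' @return Character vector of lobe labels, length \code{n_rois}.
#' @export
synthetic_lobe_map <- function(n_rois = 85) {
  lobes <- c("frontal", "temporal", "parietal", "occipital", "subcortical")
  sizes <- diff(round(seq(0, n_rois, length.out = length(lobes) + 1)))
  rep(lobes, times = sizes)
}
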
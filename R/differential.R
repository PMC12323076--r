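# Differential expression / accumulation calling. DEGs: median-of-ratios
# normalization, Welch t on log2(x+1), Benjamini-Hochberg adjustment,
# thresholds p-adjust <= 0.05 and |log2FC| >= 0.58 (fold change >= 1.5 or
# <= 0.67). DAMs: OPLS-DA VIP >= 1 plus paired t p <= 0.05, with an optional
# fold-change tier.

#' Median-of-ratios sample normalization
#'
#' Computes per-sample size factors as the median, over genes positive in
#' every sample, of the ratio of the count to the gene's geometric mean,
#' then divides each column by its factor. Factors are rescaled to have
#' geometric mean 1.
#'
#' @param counts Genes x samples count matrix (>= 2 samples).
#' @return List with `normalized` (real-valued matrix) and `size_factors`.
#' @export
median_of_ratios_normalize <- function(counts) {
  check_matrix(counts, "counts")
  if (ncol(counts) < 2L) stop2("need >= 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop2("no gene is positive in all samples")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L,
              function(col) stats::median(exp(log(col) - logg)))
  sf <- sf / exp(mean(log(sf)))
  list(normalized = sweep(counts, 2L, sf, "/"),
       size_factors = stats::setNames(sf, colnames(counts)))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Implements the step-up definition directly: with p-values sorted
#' ascending, `padj_(i) = min_(j >= i) min(1, m * p_(j) / j)`, mapped back
#' to input order (ties resolved by stable sort on (p, input index)).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop2("p-values must be in [0, 1]")
  m <- length(p)
  ord <- order(p, seq_along(p))
  scaled <- pmin(1, m * p[ord] / seq_len(m))
  padj_sorted <- rev(cummin(rev(scaled)))
  padj <- numeric(m)
  padj[ord] <- padj_sorted
  padj
}

#' Call differentially expressed genes at one time point
#'
#' Per gene: `log2fc = log2((mean_UVA + c) / (mean_CK + c))` with pseudocount
#' `c = 1` on the normalized scale; p from a Welch two-sample t test on
#' log2(x + 1); BH adjustment across genes; significant iff
#' `padj <= alpha` and `|log2fc| >= lfc_threshold`.
#'
#' @param norm Normalized genes x samples matrix.
#' @param design Design table covering the matrix columns.
#' @param timepoint Time point to contrast (UVA vs CK).
#' @param lfc_threshold Minimum absolute log2 fold change (0.58, i.e. fold
#'   change 1.5).
#' @param alpha Maximum adjusted p.
#' @param pseudocount Added to group means before the log ratio.
#' @return data.frame: feature, log2fc, p, padj, significant.
#' @export
test_deg <- function(norm, design, timepoint, lfc_threshold = 0.58,
                     alpha = 0.05, pseudocount = 1) {
  check_matrix(norm, "norm")
  check_design(design)
  if (!timepoint %in% design$timepoint)
    stop2("timepoint '", timepoint, "' absent from design")
  sel <- design[design$timepoint == timepoint, ]
  uva <- sel$sample_id[sel$treatment == "UVA"]
  ck <- sel$sample_id[sel$treatment == "CK"]
  if (length(uva) < 2L || length(ck) < 2L)
    stop2("need >= 2 replicates per group at ", timepoint)
  if (!all(c(uva, ck) %in% colnames(norm)))
    stop2("design samples missing from matrix")
  xu <- norm[, uva, drop = FALSE]
  xc <- norm[, ck, drop = FALSE]
  log2fc <- log2((rowMeans(xu) + pseudocount) /
                   (rowMeans(xc) + pseudocount))
  lu <- log2(xu + 1)
  lc <- log2(xc + 1)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    if (stats::sd(lu[i, ]) == 0 && stats::sd(lc[i, ]) == 0)
      return(if (mean(lu[i, ]) == mean(lc[i, ])) 1 else 0)
    stats::t.test(lu[i, ], lc[i, ])$p.value
  }, numeric(1))
  padj <- benjamini_hochberg(p)
  data.frame(feature = rownames(norm), log2fc = log2fc, p = p, padj = padj,
             significant = padj <= alpha & abs(log2fc) >= lfc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Union of DEGs across time points
#'
#' Convenience wrapper running [test_deg()] at each time point and returning
#' the union of significant genes, the input set for module detection.
#'
#' @inheritParams test_deg
#' @param timepoints Time points to test (default: all in the design).
#' @return Character vector of gene ids.
#' @export
deg_union <- function(norm, design, timepoints = unique(design$timepoint),
                      lfc_threshold = 0.58, alpha = 0.05) {
  sig <- lapply(timepoints, function(tp) {
    r <- test_deg(norm, design, tp, lfc_threshold, alpha)
    r$feature[r$significant]
  })
  sort(unique(unlist(sig)))
}

#' Fit a two-class OPLS-DA model
#'
#' Autoscales X (column centering, unit variance), centers the binary y,
#' iteratively removes `n_orthogonal` y-orthogonal components (systematic
#' variation in X uncorrelated with class), then fits a single predictive
#' PLS1 component on the filtered X by NIPALS.
#'
#' @param X Samples x features numeric matrix (n >= 4).
#' @param y Binary class vector (two levels; numeric, factor or character).
#' @param n_orthogonal Number of orthogonal components to remove.
#' @return An `opls_model` with predictive weights `w` (unit norm), scores
#'   `t`, loadings `p`, y-loading `q`, orthogonal `w_ortho`/`t_ortho`/
#'   `p_ortho`, per-component explained y-variance `ssy`, and the scaling
#'   used.
#' @export
fit_opls_da <- function(X, y, n_orthogonal = 1) {
  X <- as.matrix(X)
  if (nrow(X) < 4L) stop2("need >= 4 samples")
  yf <- as.numeric(factor(y))
  if (length(unique(yf)) != 2L) stop2("y must have exactly 2 classes")
  yc <- yf - mean(yf)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  if (any(sdv == 0))
    stop2("zero-variance feature(s): drop or jitter before fitting: ",
          paste(utils::head(colnames(X)[sdv == 0], 3L), collapse = ", "))
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  Xf <- Xs
  w_o <- t_o <- p_o <- NULL
  w <- drop(crossprod(Xf, yc))
  if (sqrt(sum(w^2)) < 1e-12) stop2("y has no covariance with X (degenerate)")
  w <- w / sqrt(sum(w^2))
  n_removed <- 0L
  for (a in seq_len(n_orthogonal)) {
    tt <- drop(Xf %*% w)
    pp <- drop(crossprod(Xf, tt)) / sum(tt^2)
    wo <- pp - drop(crossprod(w, pp)) * w
    if (sqrt(sum(wo^2)) < 1e-10) break  # no orthogonal variation left
    wo <- wo / sqrt(sum(wo^2))
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    w_o <- cbind(w_o, wo); t_o <- cbind(t_o, to); p_o <- cbind(p_o, po)
    n_removed <- n_removed + 1L
    w <- drop(crossprod(Xf, yc))
    w <- w / sqrt(sum(w^2))
  }
  tt <- drop(Xf %*% w)
  pp <- drop(crossprod(Xf, tt)) / sum(tt^2)
  qq <- sum(yc * tt) / sum(tt^2)
  ssy <- qq^2 * sum(tt^2)  # y variance captured by the predictive component
  structure(list(w = w, t = tt, p = pp, q = qq, ssy = ssy,
                 w_ortho = w_o, t_ortho = t_o, p_ortho = p_o,
                 n_predictive = 1L, n_orthogonal = n_removed,
                 center = mu, scale = sdv, y = yc,
                 features = colnames(X)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("OPLS-DA model: 1 predictive +", x$n_orthogonal,
      "orthogonal component(s),", length(x$w), "features\n")
  invisible(x)
}

#' Variable importance in projection (VIP) scores
#'
#' VIP on the predictive component:
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` over the predictive
#' component(s). With a single predictive component and unit-norm weights
#' this normalizes so that `mean(VIP^2) = 1`.
#'
#' @param model An `opls_model`.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  if (sum(model$ssy) <= 0) stop2("model explains no y variance (SSY = 0)")
  nfeat <- length(model$w)
  vip <- sqrt(nfeat * (model$ssy * model$w^2) / sum(model$ssy))
  stats::setNames(vip, model$features)
}

#' Call differentially accumulated metabolites at one time point
#'
#' Mirrors the two-stage metabolomics screen: multivariate importance from an
#' OPLS-DA model on log2 abundances (VIP >= `vip_min`) combined with a
#' univariate paired t test (p <= `p_max`, replicates paired by index), and
#' a second tier additionally requiring `|log2FC| >= lfc_min`.
#'
#' @param metab Metabolites x samples abundance matrix (positive values).
#' @param design Design table.
#' @param timepoint Time point to contrast.
#' @param vip_min Minimum VIP.
#' @param p_max Maximum paired-t p.
#' @param lfc_min Minimum |log2FC| for the fold-change tier.
#' @param n_orthogonal Orthogonal components for the OPLS-DA fit.
#' @return data.frame: feature, log2fc, vip, p, dam (VIP+p tier),
#'   dam_fc (VIP+p+FC tier).
#' @export
call_dams <- function(metab, design, timepoint, vip_min = 1.0, p_max = 0.05,
                      lfc_min = 0.58, n_orthogonal = 1) {
  check_matrix(metab, "metab")
  check_design(design)
  if (!timepoint %in% design$timepoint)
    stop2("timepoint '", timepoint, "' absent from design")
  sel <- design[design$timepoint == timepoint, ]
  sel <- sel[order(sel$treatment, sel$replicate), ]
  uva <- sel[sel$treatment == "UVA", ]
  ck <- sel[sel$treatment == "CK", ]
  if (nrow(uva) != nrow(ck) || !all(uva$replicate == ck$replicate))
    stop2("paired test needs balanced replicates at ", timepoint)
  xu <- metab[, uva$sample_id, drop = FALSE]
  xc <- metab[, ck$sample_id, drop = FALSE]
  lu <- log2(xu)
  lc <- log2(xc)
  log2fc <- rowMeans(lu) - rowMeans(lc)
  p <- vapply(seq_len(nrow(metab)), function(i) {
    d <- lu[i, ] - lc[i, ]
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    stats::t.test(lu[i, ], lc[i, ], paired = TRUE)$p.value
  }, numeric(1))
  X <- t(log2(metab[, sel$sample_id, drop = FALSE]))
  model <- fit_opls_da(X, sel$treatment, n_orthogonal = n_orthogonal)
  vip <- vip_scores(model)
  dam <- vip >= vip_min & p <= p_max
  data.frame(feature = rownames(metab), log2fc = log2fc, vip = unname(vip),
             p = p, dam = unname(dam),
             dam_fc = unname(dam & abs(log2fc) >= lfc_min),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,trt - Ct_ref,trt) - (Ct_target,ctl - Ct_ref,ctl)]`, the
#' standard qPCR fold change of a target gene versus a housekeeping
#' reference, treatment relative to control.
#'
#' @param ct_target_trt,ct_ref_trt Target and reference Ct under treatment.
#' @param ct_target_ctl,ct_ref_ctl Target and reference Ct under control.
#' @return Fold change (numeric).
#' @export
ddct_fold_change <- function(ct_target_trt, ct_ref_trt,
                             ct_target_ctl, ct_ref_ctl) {
  stopifnot(is.finite(ct_target_trt), is.finite(ct_ref_trt),
            is.finite(ct_target_ctl), is.finite(ct_ref_ctl))
  2^-((ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl))
}
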
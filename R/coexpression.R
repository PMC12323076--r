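# Coexpression module detection in the WGCNA style, implemented in-package:
# unsigned soft-threshold adjacency |r|^beta, topological overlap, average-
# linkage clustering with a static height cut, module eigengenes, merging of
# close modules, kME filtering, and module-trait correlation. Defaults mirror
# the study settings: beta 13, min module size 30, merge cut height 0.25,
# min kME 0.3.

#' Log2(x + 1) expression transform with mean filter
#'
#' Standard input preparation for module detection: keep genes whose mean
#' (pre-log, e.g. normalized count or FPKM-like) expression is at least
#' `min_mean`, then take log2(x + 1).
#'
#' @param norm Genes x samples nonnegative matrix.
#' @param min_mean Minimum mean expression on the pre-log scale.
#' @return Filtered, transformed matrix.
#' @export
log2_filter <- function(norm, min_mean = 1) {
  check_matrix(norm, "norm")
  keep <- rowMeans(norm) >= min_mean
  log2(norm[keep, , drop = FALSE] + 1)
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` with unit diagonal. Zero-variance genes are
#' dropped with a warning.
#'
#' @param expr Genes x samples matrix (log scale), >= 4 samples.
#' @param beta Soft-thresholding power (integer >= 1; default 13).
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
soft_adjacency <- function(expr, beta = 13) {
  check_matrix(expr, "expr")
  if (beta < 1) stop2("beta must be >= 1")
  if (ncol(expr) < 4L) stop2("need >= 4 samples")
  v <- apply(expr, 1L, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) dropped")
    expr <- expr[v > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' the sum runs over u != i, j and `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`.
#'
#' @param A Adjacency matrix from [soft_adjacency()].
#' @return TOM similarity matrix in \[0, 1\].
#' @export
topological_overlap <- function(A) {
  if (!isSymmetric(unname(A), tol = 1e-10)) stop2("adjacency must be symmetric")
  diag(A) <- 0
  k <- rowSums(A)
  shared <- A %*% A  # includes u = i and u = j terms, both zero off-diagonal
  num <- shared + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Cut a TOM dissimilarity tree into modules
#'
#' Average-linkage hierarchical clustering of `dissTOM = 1 - TOM`, cut at a
#' fixed fraction of the maximum merge height. Clusters smaller than
#' `min_size` become unassigned (label 0); the rest are labeled 1..K by
#' decreasing size.
#'
#' @param dissTOM Square dissimilarity matrix (1 - TOM).
#' @param min_size Minimum module size (default 30).
#' @param cut_height_frac Cut height as a fraction of the tallest merge.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
cut_modules <- function(dissTOM, min_size = 30, cut_height_frac = 0.99) {
  stopifnot(nrow(dissTOM) == ncol(dissTOM))
  genes <- rownames(dissTOM)
  if (nrow(dissTOM) < min_size) {
    warning("fewer than min_size genes; all unassigned")
    return(stats::setNames(integer(nrow(dissTOM)), genes))
  }
  hc <- stats::hclust(stats::as.dist(dissTOM), method = "average")
  # epsilon guards the degenerate all-identical case where heights are 0
  # up to floating noise
  h <- cut_height_frac * max(hc$height) + 1e-10
  raw <- stats::cutree(hc, h = h)
  relabel_by_size(raw, min_size, genes)
}

# keep clusters >= min_size, relabel 1..K by decreasing size, rest 0
relabel_by_size <- function(raw, min_size, genes) {
  tab <- sort(table(raw[raw > 0]), decreasing = TRUE)
  keep <- names(tab)[tab >= min_size]
  labels <- integer(length(raw))
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  stats::setNames(labels, genes)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-gene z-scored submatrix across samples, normalized to unit length and
#' sign-oriented so its correlation with the module's mean expression
#' profile is nonnegative. A single-gene module's eigengene is that gene's
#' z-profile (unit norm).
#'
#' @param expr Genes x samples matrix (log scale).
#' @param labels Module labels from [cut_modules()].
#' @return Samples x modules matrix; columns named by module label.
#' @export
module_eigengene <- function(expr, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop2("no modules to summarize")
  out <- matrix(NA_real_, ncol(expr), length(mods),
                dimnames = list(colnames(expr), as.character(mods)))
  for (m in mods) {
    sub <- expr[names(labels)[labels == m], , drop = FALSE]
    z <- t(scale(t(sub)))
    z[!is.finite(z)] <- 0
    if (nrow(z) == 1L) {
      e <- drop(z)
    } else {
      sv <- svd(z, nu = 0L, nv = 1L)
      e <- sv$v[, 1L]
    }
    e <- e / sqrt(sum(e^2))
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    out[, as.character(m)] <- e
  }
  out
}

#' Merge modules with similar eigengenes
#'
#' Average-linkage clustering of eigengenes under dissimilarity
#' `1 - cor`; branches below `cut_height` are merged, eigengenes are
#' recomputed, and the procedure iterates until no further merge occurs.
#'
#' @param expr Genes x samples matrix.
#' @param labels Module labels.
#' @param cut_height Maximum eigengene dissimilarity to merge (default 0.25).
#' @param min_size Relabeling threshold applied after merging.
#' @return List with `labels` (relabeled 1..K by decreasing size) and
#'   `eigengenes`.
#' @export
merge_close_modules <- function(expr, labels, cut_height = 0.25,
                                min_size = 2) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2L) break
    me <- module_eigengene(expr, labels)
    diss <- 1 - stats::cor(me)
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    if (max(grp) == length(mods)) break  # nothing to merge
    new <- labels
    for (g in unique(grp)) {
      members <- as.integer(names(grp)[grp == g])
      new[labels %in% members] <- members[1L]
    }
    labels <- new
  }
  labels <- relabel_by_size(labels, min_size, names(labels))
  list(labels = labels,
       eigengenes = if (any(labels > 0)) module_eigengene(expr, labels)
                    else NULL)
}

#' Filter genes by module membership (kME)
#'
#' kME of a gene is the correlation of its z-profile with its own module's
#' eigengene; genes with |kME| below `min_kme` are reassigned to label 0.
#'
#' @param expr Genes x samples matrix.
#' @param labels Module labels.
#' @param eigengenes Samples x modules eigengene matrix.
#' @param min_kme Minimum |kME| to stay (default 0.3).
#' @return Updated label vector.
#' @export
kme_filter <- function(expr, labels, eigengenes, min_kme = 0.3) {
  out <- labels
  for (g in names(labels)[labels > 0]) {
    m <- as.character(labels[[g]])
    kme <- stats::cor(expr[g, ], eigengenes[, m])
    if (!is.finite(kme) || abs(kme) < min_kme) out[[g]] <- 0L
  }
  out
}

#' Module-trait correlation
#'
#' Traits are binary indicators, one per treatment x time group (8 at the
#' default design). Reports the Pearson correlation of each eigengene with
#' each indicator and a two-sided p from `t = r sqrt(n-2) / sqrt(1-r^2)`
#' with n - 2 degrees of freedom.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengene()].
#' @param design Design table matching the eigengene rows.
#' @return data.frame: module, trait, r, p.
#' @export
module_trait_correlation <- function(eigengenes, design) {
  check_design(design)
  n <- nrow(eigengenes)
  if (n < 4L) stop2("need >= 4 samples")
  design <- design[match(rownames(eigengenes), design$sample_id), ]
  if (anyNA(design$sample_id)) stop2("eigengene samples missing from design")
  groups <- unique(paste(design$treatment, design$timepoint, sep = "_"))
  grp <- paste(design$treatment, design$timepoint, sep = "_")
  out <- NULL
  for (m in colnames(eigengenes)) {
    for (g in groups) {
      r <- stats::cor(eigengenes[, m], as.numeric(grp == g))
      p <- cor_pvalue(r, n)
      out <- rbind(out, data.frame(module = m, trait = g, r = r, p = p,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# two-sided p for a Pearson r at sample size n (t distribution, df = n - 2)
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Detect coexpression modules end to end
#'
#' Adjacency -> TOM -> static tree cut -> merge close modules -> kME filter,
#' with the study defaults (beta 13, min size 30, merge cut 0.25, min kME
#' 0.3).
#'
#' @param expr Genes x samples matrix (log2 scale, pre-filtered).
#' @param beta Soft power.
#' @param min_size Minimum module size.
#' @param merge_cut Eigengene dissimilarity below which modules merge.
#' @param min_kme Minimum |kME| to stay in a module.
#' @param cut_height_frac Static tree-cut height fraction.
#' @return List: labels, eigengenes.
#' @export
detect_modules <- function(expr, beta = 13, min_size = 30, merge_cut = 0.25,
                           min_kme = 0.3, cut_height_frac = 0.99) {
  A <- soft_adjacency(expr, beta = beta)
  tom <- topological_overlap(A)
  labels <- cut_modules(1 - tom, min_size = min_size,
                        cut_height_frac = cut_height_frac)
  expr <- expr[rownames(A), , drop = FALSE]
  if (!any(labels > 0))
    return(list(labels = labels, eigengenes = NULL))
  merged <- merge_close_modules(expr, labels, cut_height = merge_cut,
                                min_size = min_size)
  labels <- merged$labels
  if (!any(labels > 0)) return(list(labels = labels, eigengenes = NULL))
  labels <- kme_filter(expr, labels, merged$eigengenes, min_kme = min_kme)
  labels <- relabel_by_size(labels, min_size, names(labels))
  eg <- if (any(labels > 0)) module_eigengene(expr, labels) else NULL
  list(labels = labels, eigengenes = eg)
}
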
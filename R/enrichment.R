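# Hypergeometric over-representation tests of gene lists against gene-set
# collections, with Benjamini-Hochberg adjustment across sets. The p-value
# is the upper tail including the observed overlap, P(X >= k).

#' Hypergeometric gene-set over-representation test
#'
#' For each set: given a universe of N genes of which K belong to the set,
#' and a query list of n genes with overlap k, the p-value is
#' `sum_{i=k}^{min(n,K)} C(K,i) C(N-K, n-i) / C(N,n)`. P-values are adjusted
#' across sets with [benjamini_hochberg()] and rows sorted by p.
#'
#' @param gene_list Character vector of query genes (members outside the
#'   universe are dropped with a warning).
#' @param sets Gene-set collection from [read_gmt()].
#' @param universe Character vector of background gene ids (unique).
#' @return data.frame: set_id, description, k, n, K, N, p, padj.
#' @export
hypergeom_enrich <- function(gene_list, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop2("empty universe")
  gene_list <- unique(gene_list)
  out <- setdiff(gene_list, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside universe dropped")
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$genes, universe)
    K <- length(members)
    k <- length(intersect(gene_list, members))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, description = sets[[id]]$description,
               k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- benjamini_hochberg(res$p)
  res <- res[order(res$p, res$set_id), ]
  rownames(res) <- NULL
  res
}
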
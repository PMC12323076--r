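# Regulatory network assembly: TF -> structural-gene edges require (i) a
# motif hit in the target's promoter at the FIMO-style p <= 1e-4 threshold,
# (ii) a strong significant expression correlation (|PCC| >= 0.8, p <= 0.01
# by default; the looser PCC >= 0.5 screen is available via `min_abs_r`),
# and (iii) the TF belonging to an allowed coexpression module.

#' Significant TF-target expression correlations
#'
#' All TF x target pairs whose Pearson correlation across samples satisfies
#' `|r| >= min_abs_r` with two-sided t-based p <= `alpha`. Self-pairs are
#' excluded.
#'
#' @param expr Genes x samples matrix (log2 scale) covering all listed genes.
#' @param tfs,targets Character vectors of gene ids.
#' @param min_abs_r Minimum |r| (default 0.8).
#' @param alpha Maximum correlation p (default 0.01).
#' @return data.frame: tf, target, r, p.
#' @export
pearson_edges <- function(expr, tfs, targets, min_abs_r = 0.8,
                          alpha = 0.01) {
  check_matrix(expr, "expr")
  missing <- setdiff(c(tfs, targets), rownames(expr))
  if (length(missing))
    stop2("genes absent from expr: ", paste(utils::head(missing, 5L),
                                            collapse = ", "))
  if (ncol(expr) < 4L) stop2("need >= 4 samples")
  n <- ncol(expr)
  r <- stats::cor(t(expr[tfs, , drop = FALSE]),
                  t(expr[targets, , drop = FALSE]))
  out <- NULL
  for (i in seq_along(tfs)) {
    for (j in seq_along(targets)) {
      if (tfs[i] == targets[j]) next
      rij <- r[i, j]
      if (!is.finite(rij) || abs(rij) < min_abs_r) next
      p <- cor_pvalue(rij, n)
      if (p > alpha) next
      out <- rbind(out, data.frame(tf = tfs[i], target = targets[j],
                                   r = rij, p = p, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(tf = character(), target = character(), r = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the TF -> structural-gene regulatory network
#'
#' An edge tf -> target exists iff the TF is in the catalog, its module is in
#' `allowed_modules`, the best (minimum p) motif hit of the TF's motif in the
#' target's promoter has `pvalue <= p_max`, and the pair passed the
#' correlation screen. Each edge carries the best hit and correlation fields
#' plus a candidate sign from the correlation (activating if r > 0).
#'
#' @param motif_hits Hit table from [scan_promoters()] (motif ids must be TF
#'   gene ids; seq ids target gene ids).
#' @param corr_edges Correlation table from [pearson_edges()].
#' @param modules Named module label vector (from [detect_modules()]).
#' @param allowed_modules Module labels whose TFs may regulate.
#' @param catalog data.frame with columns gene, family (the TF catalog).
#' @param p_max Maximum motif p-value.
#' @return Edge data.frame: tf, target, family, module, pcc, pcc_p, motif_p,
#'   motif_start, strand, edge_sign.
#' @export
assemble_regulatory_network <- function(motif_hits, corr_edges, modules,
                                        allowed_modules, catalog,
                                        p_max = 1e-4) {
  stopifnot(all(c("gene", "family") %in% names(catalog)))
  no_motif <- setdiff(catalog$gene, unique(motif_hits$motif_id))
  if (length(no_motif))
    warning("TF(s) without any motif hit, excluded: ",
            paste(utils::head(no_motif, 5L), collapse = ", "))
  out <- NULL
  for (i in seq_len(nrow(corr_edges))) {
    tf <- corr_edges$tf[i]
    target <- corr_edges$target[i]
    if (!tf %in% catalog$gene) next
    mod <- modules[[tf]] %||% NA_integer_
    if (is.na(mod) || !mod %in% allowed_modules) next
    hits <- motif_hits[motif_hits$motif_id == tf &
                         motif_hits$seq_id == target &
                         motif_hits$pvalue <= p_max, , drop = FALSE]
    if (!nrow(hits)) next
    best <- hits[which.min(hits$pvalue), ]
    out <- rbind(out, data.frame(
      tf = tf, target = target,
      family = catalog$family[match(tf, catalog$gene)],
      module = mod,
      pcc = corr_edges$r[i], pcc_p = corr_edges$p[i],
      motif_p = best$pvalue, motif_start = best$start, strand = best$strand,
      edge_sign = if (corr_edges$r[i] > 0) "activating-candidate"
                  else "repressing-candidate",
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(tf = character(), target = character(),
                      family = character(), module = integer(),
                      pcc = numeric(), pcc_p = numeric(), motif_p = numeric(),
                      motif_start = integer(), strand = character(),
                      edge_sign = character(), stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$target), ]
  rownames(out) <- NULL
  out
}

#' Rank TF hubs and tally families per module
#'
#' @param network Edge table from [assemble_regulatory_network()].
#' @param catalog TF catalog (gene, family).
#' @return List: `hubs` (tf, out_degree, family; degree-descending, ties by
#'   id) and `family_tally` (module, family, n_tfs).
#' @export
hub_ranking <- function(network, catalog) {
  if (nrow(network) == 0L)
    return(list(hubs = data.frame(tf = character(), out_degree = integer(),
                                  family = character(),
                                  stringsAsFactors = FALSE),
                family_tally = data.frame(module = integer(),
                                          family = character(),
                                          n_tfs = integer(),
                                          stringsAsFactors = FALSE)))
  deg <- table(network$tf)
  hubs <- data.frame(tf = names(deg), out_degree = as.integer(deg),
                     stringsAsFactors = FALSE)
  hubs$family <- catalog$family[match(hubs$tf, catalog$gene)]
  hubs <- hubs[order(-hubs$out_degree, hubs$tf), ]
  rownames(hubs) <- NULL
  u <- unique(network[, c("tf", "module", "family")])
  tally <- stats::aggregate(list(n_tfs = u$tf),
                            by = list(module = u$module, family = u$family),
                            FUN = length)
  tally <- tally[order(tally$module, -tally$n_tfs, tally$family), ]
  rownames(tally) <- NULL
  list(hubs = hubs, family_tally = tally)
}

#' Cross-class signaling correlation network
#'
#' Correlation network connecting signaling genes (e.g. light and hormone
#' signal transduction), candidate TFs and structural biosynthesis genes:
#' all cross-class pairs with `|r| >= min_abs_r`. Node classes take
#' precedence signaling > TF > structural when a gene appears in several.
#'
#' @param expr Genes x samples matrix.
#' @param signaling,tfs,structural Character vectors of gene ids.
#' @param min_abs_r Minimum |r| (default 0.8).
#' @return List: `edges` (gene_a, class_a, gene_b, class_b, r) and `nodes`
#'   (gene, class).
#' @export
signaling_correlation_network <- function(expr, signaling, tfs, structural,
                                          min_abs_r = 0.8) {
  check_matrix(expr, "expr")
  cls <- c(stats::setNames(rep("structural", length(structural)), structural),
           stats::setNames(rep("tf", length(tfs)), tfs),
           stats::setNames(rep("signaling", length(signaling)), signaling))
  cls <- cls[!duplicated(names(cls), fromLast = TRUE)]  # precedence order
  for (nm in c("signaling", "tf", "structural"))
    if (!any(cls == nm)) warning("empty class: ", nm)
  genes <- intersect(names(cls), rownames(expr))
  if (length(setdiff(names(cls), genes)))
    stop2("genes absent from expr: ",
          paste(utils::head(setdiff(names(cls), genes), 5L), collapse = ", "))
  r <- stats::cor(t(expr[genes, , drop = FALSE]))
  out <- NULL
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      if (cls[[genes[i]]] == cls[[genes[j]]]) next
      if (abs(r[i, j]) < min_abs_r) next
      out <- rbind(out, data.frame(gene_a = genes[i],
                                   class_a = cls[[genes[i]]],
                                   gene_b = genes[j],
                                   class_b = cls[[genes[j]]],
                                   r = r[i, j], stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(gene_a = character(), class_a = character(),
                      gene_b = character(), class_b = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  list(edges = out,
       nodes = data.frame(gene = genes,
                          class = unname(cls[genes]),
                          stringsAsFactors = FALSE))
}
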
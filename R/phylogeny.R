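# Neighbor-joining phylogenies with bootstrap support from pre-aligned
# protein sequences: p-distances with pairwise gap deletion, Saitou-Nei NJ
# with deterministic tie-breaking, and column-resampling bootstrap whose
# supports annotate the original tree's internal edges.

#' Read a pre-aligned FASTA alignment
#'
#' @param path Aligned FASTA (protein or DNA; '-' for gaps).
#' @return Named character vector of equal-length uppercase rows.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop2("alignment: duplicate id")
  rows <- toupper(as.character(ss))
  if (length(unique(nchar(rows))) != 1L)
    stop2("alignment rows have unequal lengths")
  stats::setNames(rows, ids)
}

aln_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Pairwise p-distances with pairwise gap deletion
#'
#' `d_ij` = proportion of mismatching sites among columns where neither row
#' has a gap. A pair with no comparable column is an error.
#'
#' @param aln Named character vector of aligned rows (see
#'   [read_alignment()]) or a character matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  m <- if (is.matrix(aln)) aln else aln_char_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  ok <- m != "-"
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop2("no comparable columns between ", rownames(m)[i], " and ",
              rownames(m)[j])
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

# canonical key of a bipartition: the side not containing the first taxon,
# sorted and pasted
bipartition_key <- function(leafset, all_taxa) {
  side <- if (all_taxa[1L] %in% leafset) setdiff(all_taxa, leafset) else leafset
  paste(sort(side), collapse = "|")
}

# core NJ: returns newick template (internal nodes tagged __BPi__), and the
# bipartition key of each internal edge
nj_core <- function(D, quiet = TRUE) {
  taxa <- rownames(D)
  n <- length(taxa)
  if (n < 3L) stop2("NJ needs >= 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop2("distance matrix not symmetric")
  nw <- stats::setNames(taxa, taxa)
  leafsets <- stats::setNames(as.list(taxa), taxa)
  bp <- character(0)
  key_i <- 0L
  clamp <- function(li, lj, dij) {
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_names <- apply(cand, 1L, function(ij)
      paste(sort(rownames(D)[ij]), collapse = "\r"))
    pick <- cand[order(pair_names)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    ni <- rownames(D)[i]; nj <- rownames(D)[j]
    dij <- D[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0 || lj < 0) {
      if (!quiet) message("negative NJ branch clamped at (", ni, ",", nj, ")")
      ll <- clamp(li, lj, dij); li <- ll[1L]; lj <- ll[2L]
    }
    key_i <- key_i + 1L
    key <- sprintf("__BP%06d__", key_i)  # fixed width: no prefix collisions
    new_id <- paste0("node", key_i)
    new_leafset <- c(leafsets[[ni]], leafsets[[nj]])
    bp[key] <- bipartition_key(new_leafset, taxa)
    nw[new_id] <- sprintf("(%s:%.17g,%s:%.17g)%s", nw[ni], li, nw[nj], lj, key)
    leafsets[[new_id]] <- new_leafset
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - dij) / 2
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_id
    nw <- nw[setdiff(names(nw), c(ni, nj))]
    leafsets[[ni]] <- leafsets[[nj]] <- NULL
  }
  ids <- rownames(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  template <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                      nw[ids[1]], lens[1], nw[ids[2]], lens[2],
                      nw[ids[3]], lens[3])
  list(template = template, bipartitions = bp, taxa = taxa)
}

# drop non-informative bipartitions (size < 2 or > n - 2 on the canonical
# side is impossible by construction of internal joins, but leaf joins of
# the final trifurcation are not recorded anyway)
informative_bps <- function(core) {
  sizes <- lengths(strsplit(core$bipartitions, "|", fixed = TRUE))
  core$bipartitions[sizes >= 2 & sizes <= length(core$taxa) - 2]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei NJ: iteratively joins the pair minimizing
#' `Q_ij = (r-2) d_ij - sum_k d_ik - sum_k d_jk`, with branch lengths from
#' the standard two-point formulas. Ties on Q are broken by the
#' lexicographically smallest taxa pair; negative branch lengths are clamped
#' to zero with the deficit moved to the sibling edge.
#'
#' @param D Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An [ape::phylo] unrooted tree.
#' @export
neighbor_joining <- function(D) {
  core <- nj_core(D)
  nw <- core$template
  for (k in names(core$bipartitions)) nw <- sub(k, "", nw, fixed = TRUE)
  ape::read.tree(text = nw)
}

#' NJ tree with bootstrap support
#'
#' Resamples alignment columns with replacement `n_reps` times, recomputes
#' p-distance + NJ, and annotates each internal edge of the original tree
#' with the percentage of replicates containing the same bipartition.
#'
#' @param aln Named character vector of aligned rows.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List: `tree` (ape::phylo with supports as node labels),
#'   `supports` (named vector, percentages in \[0, 100\]), `newick`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1) {
  m <- aln_char_matrix(aln)
  if (ncol(m) < 2L) stop2("alignment needs >= 2 columns")
  core <- nj_core(p_distance(m))
  bps <- informative_bps(core)
  counts <- stats::setNames(numeric(length(bps)), bps)
  if (n_reps > 0) {
    set.seed(seed)
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_core <- tryCatch(nj_core(p_distance(m[, cols, drop = FALSE])),
                           error = function(e) NULL)
      if (is.null(rep_core)) next
      rb <- informative_bps(rep_core)
      hit <- intersect(bps, rb)
      counts[hit] <- counts[hit] + 1
    }
    supports <- 100 * counts / n_reps
  } else {
    supports <- stats::setNames(rep(NA_real_, length(bps)), bps)
  }
  nw <- core$template
  for (k in names(core$bipartitions)) {
    val <- core$bipartitions[[k]]
    lab <- if (val %in% names(supports) && is.finite(supports[[val]]))
      sprintf("%.6g", supports[[val]]) else ""
    nw <- sub(k, lab, nw, fixed = TRUE)
  }
  list(tree = ape::read.tree(text = nw), supports = supports, newick = nw)
}
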
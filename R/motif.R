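# PWM promoter scanning with log-odds scores in bits and exact p-values from
# the score distribution under a 0-order background, the approach FIMO uses:
# log-odds entries are discretized to a fixed granularity, the distribution of
# window scores under the background is built by dynamic-programming
# convolution across motif positions, and a window's p-value is the tail
# probability at its (discretized) score.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Accepts either a probability matrix (rows summing to 1) or a count matrix,
#' regularizes it with a pseudocount so all probabilities are positive, and
#' attaches log-odds scores in bits against the background.
#'
#' Probability rows become `(p + pseudocount * b) / (1 + pseudocount)`;
#' count rows become `(n + pseudocount) / (N + 4 * pseudocount)`.
#'
#' @param mat A w x 4 nonnegative matrix, columns in A, C, G, T order.
#' @param background Background base frequencies (length 4, summing to 1).
#' @param pseudocount Regularization constant.
#' @param id Motif identifier.
#' @return An object of class `pwm` with fields id, width, probs, background
#'   and log_odds (bits).
#' @export
build_pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.001,
                      id = "motif") {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L || any(mat < 0)) stop2("PWM input must be w x 4, nonnegative")
  if (any(rowSums(mat) == 0)) stop2("PWM input has a zero row")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop2("background must be 4 positive frequencies summing to 1")
  rs <- rowSums(mat)
  if (all(abs(rs - 1) < 1e-3)) {
    probs <- sweep(mat, 1L, rs, "/")  # renormalize tiny drift first
    probs <- (probs + pseudocount * matrix(background, nrow(mat), 4L,
                                           byrow = TRUE)) / (1 + pseudocount)
  } else {
    probs <- (mat + pseudocount) / (rs + 4 * pseudocount)
  }
  dimnames(probs) <- list(NULL, DNA_BASES)
  lo <- log2(sweep(probs, 2L, background, "/"))
  structure(list(id = id, width = nrow(probs), probs = probs,
                 background = stats::setNames(background, DNA_BASES),
                 log_odds = lo),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "width", x$width, "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param pwm A `pwm` object.
#' @return A character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1L, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param pwm A `pwm` object.
#' @return A `pwm` scoring the reverse-complement site.
#' @export
pwm_reverse_complement <- function(pwm) {
  rc <- pwm
  flip <- function(m) m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
  rc$probs <- flip(pwm$probs)
  rc$log_odds <- flip(pwm$log_odds)
  dimnames(rc$probs) <- list(NULL, DNA_BASES)
  dimnames(rc$log_odds) <- list(NULL, DNA_BASES)
  rc
}

# integer-discretized log-odds (units of `granularity` bits)
pwm_int_scores <- function(pwm, granularity) {
  round(pwm$log_odds / granularity)
}

#' Exact score distribution and p-value table for a PWM
#'
#' Discretizes the log-odds to integer multiples of `granularity` bits and
#' convolves the per-position score distribution under the background model
#' (independent positions). The resulting map score -> P(score >= s) is exact
#' up to the discretization.
#'
#' @param pwm A `pwm` object.
#' @param granularity Discretization step in bits.
#' @param max_bins Safety cap on the size of the DP table.
#' @return An object of class `pwm_pvalue_table` with the integer score
#'   matrix, the attainable integer score range and the tail probabilities.
#' @export
score_pvalue_table <- function(pwm, granularity = 1e-3, max_bins = 2e7) {
  ints <- pwm_int_scores(pwm, granularity)
  lo <- sum(apply(ints, 1L, min))
  hi <- sum(apply(ints, 1L, max))
  nbin <- hi - lo + 1L
  if (nbin > max_bins)
    stop2("score range needs ", nbin, " bins (> ", max_bins,
          "); use a coarser granularity")
  # dist[k] = P(sum of discretized scores == lo + k - 1)
  dist <- numeric(nbin)
  cur_lo <- 0L
  dist[1L] <- 1
  cur_len <- 1L
  bg <- pwm$background
  for (i in seq_len(pwm$width)) {
    row <- ints[i, ]
    rmin <- min(row)
    new_len <- cur_len + (max(row) - rmin)
    new <- numeric(new_len)
    for (b in 1:4) {
      off <- row[b] - rmin
      idx <- seq_len(cur_len) + off
      new[idx] <- new[idx] + dist[seq_len(cur_len)] * bg[b]
    }
    dist <- new
    cur_lo <- cur_lo + rmin
    cur_len <- new_len
  }
  tail_p <- rev(cumsum(rev(dist)))
  tail_p <- pmin(tail_p, 1)
  structure(list(id = pwm$id, ints = ints, granularity = granularity,
                 min_sum = cur_lo, max_sum = cur_lo + cur_len - 1L,
                 tail = tail_p),
            class = "pwm_pvalue_table")
}

# p-value of an integer-discretized score sum
pvalue_int <- function(tbl, int_sum) {
  k <- int_sum - tbl$min_sum + 1L
  k <- pmin(pmax(k, 1L), length(tbl$tail) + 1L)
  out <- numeric(length(k))
  inside <- k <= length(tbl$tail)
  out[inside] <- tbl$tail[k[inside]]
  out[!inside] <- 0
  out[int_sum <= tbl$min_sum] <- 1
  out
}

#' P-value of a score in bits under a PWM's background distribution
#'
#' @param tbl A `pwm_pvalue_table`.
#' @param score Score(s) in bits.
#' @return P(window score >= score) under the background, exact up to the
#'   table's discretization (scores within half a granularity step per
#'   position of an attainable score map to that score's tail).
#' @export
pwm_pvalue <- function(tbl, score) {
  tol <- nrow(tbl$ints) * tbl$granularity / 2  # max accumulated rounding
  pvalue_int(tbl, ceiling((score - tol) / tbl$granularity))
}

# encode an ACGTN string as integers A=1..T=4, N=0
encode_dna <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T", "N"))
  m[m == 5L] <- 0L
  if (anyNA(m)) stop2("sequence contains characters outside ACGTN")
  m
}

# integer window scores of an encoded sequence; N scores 0 at its position
window_scores_int <- function(code, ints) {
  w <- nrow(ints)
  L <- length(code)
  n_win <- L - w + 1L
  if (n_win < 1L) return(integer(0))
  s <- integer(n_win)
  for (i in seq_len(w)) {
    lut <- c(0L, ints[i, ])  # index 1 = N contribution
    s <- s + lut[code[i:(n_win + i - 1L)] + 1L]
  }
  s
}

#' Scan promoters with a PWM and report significant hits
#'
#' Every window on the forward strand and (optionally) the reverse strand is
#' scored; windows whose exact background p-value is at or below `p_max` are
#' returned. Reverse-strand hits are reported at the forward coordinate of
#' the window's leftmost base. `N` bases contribute zero log-odds
#' (background-equivalent). Reverse-strand p-values use the score
#' distribution of the reverse-complemented PWM under the same background,
#' so they are exact for any background.
#'
#' @param pwm A `pwm` object or list of them.
#' @param promoters Named character vector of promoter sequences
#'   (see [read_fasta()]).
#' @param p_max P-value threshold (FIMO-style default 1e-4).
#' @param both_strands Scan the reverse strand too?
#' @param granularity Score discretization in bits.
#' @return A data.frame of hits: motif_id, seq_id, start (1-based), strand,
#'   score (bits), pvalue; sorted by (motif_id, seq_id, start, strand).
#' @export
scan_promoters <- function(pwm, promoters, p_max = 1e-4, both_strands = TRUE,
                           granularity = 1e-3) {
  if (inherits(pwm, "pwm")) pwm <- list(pwm)
  stopifnot(is.character(promoters), !is.null(names(promoters)))
  res <- list()
  for (p in pwm) {
    tbl_f <- score_pvalue_table(p, granularity)
    strands <- list(`+` = list(p, tbl_f))
    if (both_strands) {
      prc <- pwm_reverse_complement(p)
      strands$`-` <- list(prc, score_pvalue_table(prc, granularity))
    }
    for (sid in names(promoters)) {
      code <- encode_dna(promoters[[sid]])
      for (st in names(strands)) {
        ints <- strands[[st]][[2L]]$ints
        si <- window_scores_int(code, ints)
        if (!length(si)) next
        pv <- pvalue_int(strands[[st]][[2L]], si)
        keep <- which(pv <= p_max)
        if (!length(keep)) next
        res[[length(res) + 1L]] <- data.frame(
          motif_id = p$id, seq_id = sid, start = keep, strand = st,
          score = si[keep] * granularity, pvalue = pv[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(motif_id = character(), seq_id = character(),
                      start = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$motif_id, out$seq_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}
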
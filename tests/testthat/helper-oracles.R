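# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle re-derives the quantity from its definition, without
# touching the package's implementation path.

# step-up FDR from the definition: padj_i = min over j with p_(j) >= p_i of
# min(1, m * p_(j) / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    j <- which(ps >= pi - 1e-15)
    min(1, min(m * ps[j] / j))
  }, numeric(1))
}

# TOM from the triple-loop definition
tom_bruteforce <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  for (i in seq_len(n)) {
    ki <- sum(A[i, -i])
    for (j in seq_len(n)) {
      if (i == j) next
      kj <- sum(A[j, -j])
      s <- 0
      for (u in seq_len(n)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
      out[i, j] <- (s + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
    }
  }
  out
}

# exhaustive word enumeration of PWM score tail probabilities on the same
# discretized lattice the DP uses
motif_enum_pvalue <- function(pwm, int_sum, granularity = 1e-3) {
  w <- pwm$width
  ints <- round(pwm$log_odds / granularity)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  ws <- integer(nrow(words))
  wp <- rep(1, nrow(words))
  for (i in seq_len(w)) {
    ws <- ws + ints[i, words[, i]]
    wp <- wp * pwm$background[words[, i]]
  }
  vapply(int_sum, function(s) sum(wp[ws >= s]), numeric(1))
}

# upper-tail hypergeometric from the closed form
hyper_bruteforce <- function(k, K, N, n) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# adjusted Rand index (mclust's reference implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny two-group design over one time point per call site
tiny_design <- function(n_reps = 3) generate_design(n_reps)

# a PWM with dense score lattice (heterogeneous soft columns), informative
# enough that the 1e-4 tail is attainable
dense_pwm <- function(width = 10, seed = 42) {
  set.seed(seed)
  probs <- t(replicate(width, {
    x <- stats::rexp(4)^1.5 + 0.05
    x / sum(x)
  }))
  build_pwm(probs, id = "dense")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
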
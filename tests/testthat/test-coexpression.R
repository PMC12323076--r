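# Module detection: adjacency/TOM identities against hand computation and a
# brute-force oracle, planted-block recovery, eigengene and merging
# semantics, kME filtering, and the module-trait closed form.

make_block_expr <- function(n_per_block = 60, n_samples = 24, noise = 0.3,
                            n_blocks = 2, seed = 1) {
  set.seed(seed)
  lat <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks)
  x <- do.call(rbind, lapply(seq_len(n_blocks), function(b)
    matrix(rep(lat[b, ], n_per_block), n_per_block, byrow = TRUE) +
      stats::rnorm(n_per_block * n_samples, 0, noise)))
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_blocks * n_per_block)),
                      paste0("s", seq_len(n_samples)))
  x
}

test_that("soft adjacency is |r|^beta with unit diagonal", {
  s <- paste0("s", 1:6)
  x <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = c(2, 4, 6, 8, 10, 12),
             g3 = c(1, -1, 1, -1, 1, -1))
  colnames(x) <- s
  a <- soft_adjacency(x, beta = 13)
  expect_equal(a["g1", "g2"], 1)             # r = 1
  expect_equal(diag(a), rep(1, 3), ignore_attr = TRUE)
  r13 <- abs(stats::cor(x["g1", ], x["g3", ]))^13
  expect_equal(a["g1", "g3"], r13)
  expect_equal(0.9^13, 0.2541866, tolerance = 1e-6)
  expect_error(soft_adjacency(x, beta = 0), "beta")
})

test_that("TOM matches hand computation and the brute-force oracle", {
  A <- matrix(1, 3, 3)
  dimnames(A) <- list(paste0("g", 1:3), paste0("g", 1:3))
  tom <- topological_overlap(A)
  expect_equal(tom[1, 2], 1)  # (1+1)/(2+1-1)
  A0 <- diag(3)
  dimnames(A0) <- dimnames(A)
  expect_equal(topological_overlap(A0)[upper.tri(A0)], rep(0, 3))
  set.seed(4)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    M <- matrix(stats::runif(n * n), n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    dimnames(M) <- list(paste0("g", 1:n), paste0("g", 1:n))
    expect_equal(unname(topological_overlap(M)), tom_bruteforce(M),
                 tolerance = 1e-12)
  }
})

test_that("planted blocks are recovered exactly by the static cut", {
  x <- make_block_expr(60, noise = 0.35, seed = 2)
  truth <- rep(1:2, each = 60)
  mod <- detect_modules(x)
  expect_equal(length(unique(mod$labels[mod$labels > 0])), 2)
  expect_equal(ari(mod$labels, truth), 1)
})

test_that("degenerate inputs behave as documented", {
  # all-identical profiles collapse to one module
  x <- matrix(rep(seq_len(10), each = 40), 40, 10,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  labs <- cut_modules(1 - topological_overlap(soft_adjacency(x)),
                      min_size = 10)
  expect_equal(unname(labs), rep(1L, 40))
  # pure noise is predominantly unassigned at default settings
  set.seed(9)
  noise <- matrix(stats::rnorm(200 * 24), 200, 24,
                  dimnames = list(paste0("g", 1:200), paste0("s", 1:24)))
  labs2 <- detect_modules(noise)$labels
  expect_gt(mean(labs2 == 0), 0.8)
  expect_warning(cut_modules(matrix(0, 3, 3,
                                    dimnames = list(letters[1:3],
                                                    letters[1:3]))),
                 "min_size")
})

test_that("eigengenes are unit-norm, oriented, and track the latent factor", {
  x <- make_block_expr(50, noise = 0.3, n_blocks = 1, seed = 5)
  labels <- stats::setNames(rep(1L, nrow(x)), rownames(x))
  me <- module_eigengene(x, labels)
  expect_equal(sum(me[, "1"]^2), 1, tolerance = 1e-12)
  zmean <- colMeans(t(scale(t(x))))
  expect_gte(stats::cor(me[, "1"], zmean), 0)
  # eigengene recovers the planted latent profile
  set.seed(5)
  lat <- stats::rnorm(24)
  expect_gte(abs(stats::cor(me[, "1"], lat)), 0.95)
  # single-gene module falls back to that gene's z-profile
  labels1 <- stats::setNames(c(1L, rep(0L, nrow(x) - 1)), rownames(x))
  me1 <- module_eigengene(x, labels1)
  z1 <- scale(x[1, ])[, 1]
  expect_equal(abs(stats::cor(me1[, "1"], z1)), 1, tolerance = 1e-12)
})

test_that("module merging follows the eigengene dissimilarity threshold", {
  set.seed(6)
  lat <- stats::rnorm(24)
  # two modules sharing one latent (eigengene cor ~0.97): must merge
  x <- rbind(matrix(rep(lat, 40), 40, byrow = TRUE),
             matrix(rep(lat, 40), 40, byrow = TRUE)) +
    stats::rnorm(80 * 24, 0, 0.25)
  dimnames(x) <- list(paste0("g", 1:80), paste0("s", 1:24))
  labels <- stats::setNames(rep(1:2, each = 40), rownames(x))
  merged <- merge_close_modules(x, labels, cut_height = 0.25)
  expect_equal(length(unique(merged$labels[merged$labels > 0])), 1)
  # independent latents (eigengene cor ~0): must not merge
  x2 <- make_block_expr(40, noise = 0.3, seed = 7)
  labels2 <- stats::setNames(rep(1:2, each = 40), rownames(x2))
  m2 <- merge_close_modules(x2, labels2, cut_height = 0.25)
  expect_equal(length(unique(m2$labels[m2$labels > 0])), 2)
  # merging again changes nothing (idempotent at convergence)
  m3 <- merge_close_modules(x2, m2$labels, cut_height = 0.25)
  expect_equal(unname(m3$labels), unname(m2$labels))
  # single module passes through
  l1 <- stats::setNames(rep(1L, 80), rownames(x2))
  expect_equal(unname(merge_close_modules(x2, l1)$labels), rep(1L, 80))
})

test_that("kME filter reassigns weak members only", {
  x <- make_block_expr(40, noise = 0.3, n_blocks = 1, seed = 8)
  x <- rbind(x, noise1 = stats::rnorm(24))
  labels <- stats::setNames(rep(1L, nrow(x)), rownames(x))
  me <- module_eigengene(x, labels)
  out <- kme_filter(x, labels, me, min_kme = 0.3)
  expect_equal(out[["noise1"]], 0L)
  expect_true(all(out[rownames(x)[1:40]] == 1L))
  expect_equal(unname(kme_filter(x, labels, me, min_kme = 0)),
               unname(labels))
})

test_that("module-trait correlation matches the t-distribution closed form", {
  d <- generate_design(3)
  me <- matrix(0, 24, 1, dimnames = list(d$sample_id, "1"))
  ind <- as.numeric(d$treatment == "UVA" & d$timepoint == "4h")
  me[, 1] <- scale(ind)[, 1] / sqrt(23)
  mt <- module_trait_correlation(me, d)
  row <- mt[mt$trait == "UVA_4h", ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_lt(row$p, 1e-12)
  # closed form at r = 0.8, n = 24
  t <- 0.8 * sqrt(22) / sqrt(1 - 0.64)
  expect_equal(t, 6.253888, tolerance = 1e-6)
  expect_equal(uvaregnet:::cor_pvalue(0.8, 24),
               2 * stats::pt(t, 22, lower.tail = FALSE))
  expect_equal(uvaregnet:::cor_pvalue(0, 24), 1)
})

test_that("outputs are invariant to gene relabeling up to the permutation", {
  x <- make_block_expr(35, noise = 0.35, seed = 10)
  mod1 <- detect_modules(x)
  perm <- sample(nrow(x))
  mod2 <- detect_modules(x[perm, ])
  expect_equal(ari(mod1$labels[rownames(x)[perm]], mod2$labels), 1)
})
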
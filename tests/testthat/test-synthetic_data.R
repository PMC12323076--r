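# The generators must reproduce the stated experimental design, honor their
# own distributional model, and be bit-reproducible under a fixed seed.

test_that("design table matches the 2 x 4 x R layout and is deterministic", {
  d <- generate_design(3)
  expect_equal(nrow(d), 24)
  expect_equal(unname(as.vector(table(d$treatment, d$timepoint))),
               rep(3L, 8))
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_equal(nrow(generate_design(2)), 16)
  expect_identical(generate_design(3, seed = 7), generate_design(3, seed = 7))
  expect_error(generate_design(1), "n_reps")
})

test_that("expression generator honors the null model when effect is zero", {
  d <- generate_design(3)
  e <- generate_expression(d, n_genes = 400, module_sizes = c(50L, 50L),
                           effect_log2 = 0, seed = 3)
  expect_true(all(e$counts >= 0))
  expect_true(all(e$counts == round(e$counts)))
  expect_equal(nrow(e$truth$de_genes), 0)
  # empirical UVA/CK log2 ratio centered at 0 for planted genes
  uva <- d$sample_id[d$treatment == "UVA"]
  ck <- d$sample_id[d$treatment == "CK"]
  planted <- names(e$truth$module_of)[e$truth$module_of > 0]
  lr <- log2(rowMeans(e$counts[planted, uva]) /
               rowMeans(e$counts[planted, ck]))
  expect_lt(abs(mean(lr)), 0.3)
})

test_that("planted log2 effect is recovered empirically across seeds", {
  d <- generate_design(3)
  ratios <- vapply(1:20, function(s) {
    e <- generate_expression(d, n_genes = 300, module_sizes = c(40L),
                             effect_log2 = 2, seed = s,
                             responsive_modules = 1,
                             affected_timepoints = "2d")
    sel <- d[d$timepoint == "2d", ]
    uva <- sel$sample_id[sel$treatment == "UVA"]
    ck <- sel$sample_id[sel$treatment == "CK"]
    planted <- e$truth$de_genes$gene[e$truth$de_genes$timepoint == "2d"]
    mean(log2(rowMeans(e$counts[planted, uva]) /
                rowMeans(e$counts[planted, ck])))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.3)
})

test_that("counts approach the Poisson CV limit at small dispersion", {
  d <- generate_design(3)
  e <- generate_expression(d, n_genes = 500, module_sizes = integer(0),
                           dispersion = 1e-6, noise_sd = 0, seed = 4,
                           baseline_log2_mean = 10, baseline_log2_sd = 0)
  cv <- apply(e$counts, 1L, function(x) stats::sd(x) / mean(x))
  # Poisson CV at mu = 1024 is ~1/32
  expect_lt(abs(median(cv) - 1 / sqrt(1024)), 0.01)
})

test_that("expression generator validates its inputs", {
  d <- generate_design(3)
  expect_error(generate_expression(d, module_sizes = c(1L)), "module_sizes")
  expect_error(generate_expression(d, dispersion = 0), "dispersion")
  expect_error(generate_expression(d, n_genes = 10,
                                   module_sizes = c(20L)), "exceeds")
  e1 <- generate_expression(d, n_genes = 100, seed = 11,
                            module_sizes = c(30L))
  e2 <- generate_expression(d, n_genes = 100, seed = 11,
                            module_sizes = c(30L))
  expect_identical(e1, e2)
})

test_that("metabolome generator plants signed DAMs of the stated magnitude", {
  d <- generate_design(3)
  m0 <- generate_metabolome(d, n_metabolites = 50, n_dams = 0, seed = 1)
  expect_length(m0$truth$dam_metabolites, 0)
  expect_true(all(m0$abundance > 0))
  # a 20-fold planted effect yields a ~20x UVA/CK mean ratio across seeds
  ratios <- vapply(1:10, function(s) {
    m <- generate_metabolome(d, n_metabolites = 50, n_dams = 1,
                             effect_log2 = log2(20), seed = s)
    dam <- names(m$truth$dam_metabolites)[1]
    uva <- d$sample_id[d$treatment == "UVA"]
    ck <- d$sample_id[d$treatment == "CK"]
    mean(m$abundance[dam, uva]) / mean(m$abundance[dam, ck])
  }, numeric(1))
  expect_lt(abs(log2(mean(ratios)) - log2(20)), 0.5)
  expect_identical(generate_metabolome(d, seed = 5),
                   generate_metabolome(d, seed = 5))
  expect_error(generate_metabolome(d, effect_log2 = -1), "signs")
})

test_that("promoter generator plants recoverable sites on both strands", {
  lib <- demo_motif_library(c("TFa", "TFb"), seed = 2)
  pl <- data.frame(motif_id = c("TFa", "TFb"), gene = c("g1", "g1"),
                   offset = c(101L, 500L), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  pr <- generate_promoters(c("g1", "g2"), lib, pl, seed = 3,
                           consensus = TRUE)
  expect_equal(unname(nchar(pr)), c(2000L, 2000L))
  # consensus site scans back at the planted offset with the maximum score
  hits <- scan_promoters(lib[["TFa"]], pr["g1"], p_max = 1e-4)
  expect_true(any(hits$start == 101 & hits$strand == "+"))
  best <- hits[hits$start == 101 & hits$strand == "+", ]
  expect_equal(best$score, sum(apply(lib[["TFa"]]$log_odds, 1, max)),
               tolerance = 0.01)
  # reverse-strand placement found as a - strand hit at its offset
  hb <- scan_promoters(lib[["TFb"]], pr["g1"], p_max = 1e-4)
  expect_true(any(hb$start == 500 & hb$strand == "-"))
  # background-only promoters carry no planted structure
  expect_identical(
    generate_promoters("g9", seed = 8),
    generate_promoters("g9", seed = 8))
  over <- data.frame(motif_id = c("TFa", "TFb"), gene = "g1",
                     offset = c(100L, 105L), strand = "+",
                     stringsAsFactors = FALSE)
  expect_error(generate_promoters("g1", lib, over), "overlap")
  expect_error(generate_promoters("g1", lib, pl[1, ], gc = 1.2), "gc")
})

test_that("simulated dataset keeps its regulatory truth self-consistent", {
  data <- simulate_uva_dataset(seed = 6, n_genes = 600,
                               module_sizes = rep(60L, 3L))
  ed <- data$truth$regulatory_edges
  pl <- data$truth$motif_placements
  # every planted edge has a placement in its target's promoter
  expect_true(all(paste(ed$tf, ed$target) %in% paste(pl$motif_id, pl$gene)))
  # tf and target share a planted module
  mo <- data$truth$module_of
  expect_true(all(mo[ed$tf] == mo[ed$target] & mo[ed$tf] > 0))
  # tf/target expression correlation is high by construction
  lx <- log2(data$counts + 1)
  r <- vapply(seq_len(nrow(ed)), function(i)
    stats::cor(lx[ed$tf[i], ], lx[ed$target[i], ]), numeric(1))
  expect_gt(mean(abs(r)), 0.8)
})
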
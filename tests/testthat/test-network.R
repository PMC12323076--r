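# Network assembly: correlation screen semantics, exact intersection of the
# three evidence predicates, threshold monotonicity, ablation, hub ranking
# and the cross-class signaling network.

make_net_fixture <- function() {
  # 2 TFs, 3 targets; expression engineered so tf1 correlates with t1/t2
  # and tf2 with t3
  set.seed(31)
  lat1 <- stats::rnorm(24)
  lat2 <- stats::rnorm(24)
  x <- rbind(tf1 = lat1, t1 = lat1 + stats::rnorm(24, 0, 0.2),
             t2 = -lat1 + stats::rnorm(24, 0, 0.2),
             tf2 = lat2, t3 = lat2 + stats::rnorm(24, 0, 0.2))
  colnames(x) <- paste0("s", 1:24)
  hits <- data.frame(
    motif_id = c("tf1", "tf1", "tf2"),
    seq_id = c("t1", "t2", "t3"),
    start = c(10L, 20L, 30L), strand = c("+", "-", "+"),
    score = c(12, 11, 10), pvalue = c(1e-6, 5e-5, 2e-5),
    stringsAsFactors = FALSE)
  modules <- c(tf1 = 1L, t1 = 1L, t2 = 1L, tf2 = 2L, t3 = 2L)
  catalog <- data.frame(gene = c("tf1", "tf2"), family = c("MYB", "WRKY"),
                        stringsAsFactors = FALSE)
  list(x = x, hits = hits, modules = modules, catalog = catalog)
}

test_that("pearson_edges keeps strong significant pairs only", {
  f <- make_net_fixture()
  ce <- pearson_edges(f$x, c("tf1", "tf2"), c("t1", "t2", "t3"))
  keys <- paste(ce$tf, ce$target)
  expect_setequal(keys, c("tf1 t1", "tf1 t2", "tf2 t3"))
  expect_lt(ce$r[ce$tf == "tf1" & ce$target == "t2"], -0.8)  # sign kept
  # identical profile under a distinct id gives r = 1 and is retained
  x2 <- rbind(f$x, t4 = f$x["tf1", ])
  ce2 <- pearson_edges(x2, "tf1", "t4")
  expect_equal(ce2$r, 1)
  # self-pairs excluded; missing genes error
  expect_equal(nrow(pearson_edges(f$x, "tf1", "tf1")), 0)
  expect_error(pearson_edges(f$x, "tf1", "nope"), "absent")
  # threshold monotonicity: edges at 0.8 are a subset of edges at 0.5
  e08 <- pearson_edges(f$x, c("tf1", "tf2"), c("t1", "t2", "t3"),
                       min_abs_r = 0.8)
  e05 <- pearson_edges(f$x, c("tf1", "tf2"), c("t1", "t2", "t3"),
                       min_abs_r = 0.5)
  expect_true(all(paste(e08$tf, e08$target) %in% paste(e05$tf, e05$target)))
})

test_that("chance correlations rarely pass |r| >= 0.8 at n = 24", {
  set.seed(32)
  reps <- replicate(2000, stats::cor(stats::rnorm(24), stats::rnorm(24)))
  expect_lt(mean(abs(reps) >= 0.8), 1e-3)
})

test_that("assembly is the exact intersection of the evidence predicates", {
  f <- make_net_fixture()
  ce <- pearson_edges(f$x, c("tf1", "tf2"), c("t1", "t2", "t3"))
  net <- assemble_regulatory_network(f$hits, ce, f$modules,
                                     allowed_modules = c(1L, 2L),
                                     catalog = f$catalog)
  # brute-force triple filter over all tf x target pairs
  expected <- NULL
  for (tf in f$catalog$gene) {
    for (tg in c("t1", "t2", "t3")) {
      has_motif <- any(f$hits$motif_id == tf & f$hits$seq_id == tg &
                         f$hits$pvalue <= 1e-4)
      in_corr <- any(ce$tf == tf & ce$target == tg)
      mod_ok <- f$modules[[tf]] %in% c(1L, 2L)
      if (has_motif && in_corr && mod_ok)
        expected <- c(expected, paste(tf, tg))
    }
  }
  expect_setequal(paste(net$tf, net$target), expected)
  expect_equal(net$edge_sign[net$target == "t2"], "repressing-candidate")
  # module restriction removes that module's edges
  net1 <- assemble_regulatory_network(f$hits, ce, f$modules,
                                      allowed_modules = 1L,
                                      catalog = f$catalog)
  expect_true(all(net1$tf == "tf1"))
  net0 <- assemble_regulatory_network(f$hits, ce, f$modules,
                                      allowed_modules = integer(0),
                                      catalog = f$catalog)
  expect_equal(nrow(net0), 0)
  # ablation: dropping one motif hit removes exactly that edge
  net_ab <- assemble_regulatory_network(
    f$hits[-1, ], ce, f$modules, c(1L, 2L), f$catalog)
  expect_setequal(setdiff(paste(net$tf, net$target),
                          paste(net_ab$tf, net_ab$target)), "tf1 t1")
  # a TF with no motif evidence triggers a warning and contributes no edge
  expect_warning(
    assemble_regulatory_network(f$hits[f$hits$motif_id != "tf2", ], ce,
                                f$modules, c(1L, 2L), f$catalog),
    "without")
})

test_that("tightening any threshold never adds edges", {
  data <- simulate_uva_dataset(seed = 3, n_genes = 600,
                               module_sizes = rep(60L, 3L))
  nrm <- median_of_ratios_normalize(data$counts)$normalized
  expr <- log2(nrm + 1)
  tfs <- data$tf_catalog$gene
  targets <- names(data$promoters)
  hits <- scan_promoters(data$pwm_library, data$promoters, p_max = 1e-3)
  modules <- data$truth$module_of
  loose <- assemble_regulatory_network(
    hits, pearson_edges(expr, tfs, targets, 0.5, 0.05), modules,
    1:3, data$tf_catalog, p_max = 1e-3)
  tight <- assemble_regulatory_network(
    hits, pearson_edges(expr, tfs, targets, 0.8, 0.01), modules,
    1:3, data$tf_catalog, p_max = 1e-4)
  expect_true(all(paste(tight$tf, tight$target) %in%
                    paste(loose$tf, loose$target)))
})

test_that("hub ranking orders by out-degree and tallies families", {
  f <- make_net_fixture()
  ce <- pearson_edges(f$x, c("tf1", "tf2"), c("t1", "t2", "t3"))
  net <- assemble_regulatory_network(f$hits, ce, f$modules, c(1L, 2L),
                                     f$catalog)
  hr <- hub_ranking(net, f$catalog)
  expect_equal(hr$hubs$tf[1], "tf1")
  expect_equal(hr$hubs$out_degree, c(2L, 1L))
  expect_equal(sum(hr$family_tally$n_tfs), length(unique(net$tf)))
  single <- net[1, , drop = FALSE]
  hr1 <- hub_ranking(single, f$catalog)
  expect_equal(hr1$hubs$out_degree, 1L)
})

test_that("signaling network connects cross-class pairs only", {
  set.seed(33)
  lat <- stats::rnorm(24)
  x <- rbind(sigA = lat, tfB = lat + stats::rnorm(24, 0, 0.05),
             strC = lat + stats::rnorm(24, 0, 0.05),
             strD = stats::rnorm(24))
  colnames(x) <- paste0("s", 1:24)
  net <- signaling_correlation_network(x, "sigA", "tfB", c("strC", "strD"))
  expect_true(all(abs(net$edges$r) >= 0.8))
  expect_true(all(net$edges$class_a != net$edges$class_b))
  keys <- vapply(seq_len(nrow(net$edges)), function(i)
    paste(sort(c(net$edges$gene_a[i], net$edges$gene_b[i])),
          collapse = " "), character(1))
  expect_setequal(keys, c("sigA tfB", "sigA strC", "strC tfB"))
  # class precedence: a gene listed as both signaling and structural is
  # signaling
  net2 <- signaling_correlation_network(x, "sigA", "tfB",
                                        c("sigA", "strC", "strD"))
  expect_equal(net2$nodes$class[net2$nodes$gene == "sigA"], "signaling")
  expect_warning(signaling_correlation_network(x, character(0), "tfB",
                                               "strC"),
                 "empty class")
})
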
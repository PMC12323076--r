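# End-to-end orchestration: a single config drives simulation (or loading)
# of inputs, differential calling, module detection on the DEG union, motif
# scanning, network assembly and enrichment, writing one TSV per report
# table plus a run log with the resolved configuration.

#' Default pipeline configuration
#'
#' Thresholds mirror the study settings: DEG p-adjust 0.05 with |log2FC| >=
#' 0.58; DAM VIP >= 1 with paired-t p <= 0.05; soft power 13, min module
#' size 30, merge cut 0.25, min kME 0.3; motif p <= 1e-4; network
#' |PCC| >= 0.8 with p <= 0.01.
#'
#' @param ... Overrides of individual fields.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(alpha = 0.05, lfc = 0.58, vip = 1.0, beta = 13,
              min_size = 30, merge_cut = 0.25, min_kme = 0.3,
              motif_pmax = 1e-4, min_abs_r = 0.8, corr_alpha = 0.01,
              filter_min_mean = 1, seed = 1,
              n_genes = 2000, module_sizes = rep(100L, 6L),
              effect_log2 = 2, dispersion = 0.005,
              n_metabolites = 300, n_dams = 30, met_effect_log2 = 2,
              out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$beta >= 1,
            cfg$motif_pmax > 0, cfg$min_abs_r >= 0, cfg$min_abs_r <= 1)
  cfg
}

#' Sample-level PCA for quality control
#'
#' Column-centered PCA of the samples; returns scores on the first two
#' components and the fraction of variance each explains.
#'
#' @param mat Features x samples matrix (>= 3 samples).
#' @param log2p1 Apply log2(x + 1) first?
#' @return List: `scores` (samples x 2), `var_frac` (all components).
#' @export
pca_qc <- function(mat, log2p1 = TRUE) {
  check_matrix(mat, "mat")
  if (ncol(mat) < 3L) stop2("need >= 3 samples")
  x <- if (log2p1) log2(mat + 1) else mat
  x <- t(x)  # samples x features
  if (all(apply(x, 2L, stats::sd) == 0)) stop2("constant matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE], var_frac = vf)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on simulated or supplied inputs
#'
#' Stages: simulate (when no matrices are supplied) -> normalization ->
#' per-timepoint DEG tables -> DAM tables -> module detection on the DEG
#' union -> module-trait correlation -> promoter motif scan -> correlation
#' screen -> regulatory network -> hub ranking -> optional enrichment.
#' Writes every report table as TSV under `config$out_dir` (when set)
#' together with `run.log` recording the resolved configuration.
#'
#' @param config List from [default_config()].
#' @param data Optional pre-built dataset, as from [simulate_uva_dataset()];
#'   when NULL one is simulated with `config$seed`.
#' @param gene_sets Optional gene-set collection for enrichment of module
#'   genes.
#' @return A list of all result tables (invisibly writes TSVs when
#'   `out_dir` is set).
#' @export
run_all <- function(config = default_config(), data = NULL,
                    gene_sets = NULL) {
  cfg <- config
  if (is.null(data)) {
    data <- simulate_uva_dataset(
      seed = cfg$seed, n_genes = cfg$n_genes,
      module_sizes = cfg$module_sizes, effect_log2 = cfg$effect_log2,
      dispersion = cfg$dispersion, n_metabolites = cfg$n_metabolites,
      n_dams = cfg$n_dams, met_effect_log2 = cfg$met_effect_log2)
  }
  design <- data$design
  res <- list(config = cfg, design = design)

  norm <- median_of_ratios_normalize(data$counts)$normalized
  timepoints <- unique(design$timepoint)
  res$deg <- lapply(stats::setNames(timepoints, timepoints), function(tp)
    test_deg(norm, design, tp, lfc_threshold = cfg$lfc, alpha = cfg$alpha))
  degs <- sort(unique(unlist(lapply(res$deg, function(d)
    d$feature[d$significant]))))
  res$deg_union <- degs

  res$dam <- lapply(stats::setNames(timepoints, timepoints), function(tp)
    call_dams(data$abundance, design, tp, vip_min = cfg$vip,
              p_max = cfg$alpha, lfc_min = cfg$lfc))

  expr_all <- log2_filter(norm, min_mean = cfg$filter_min_mean)
  expr_deg <- expr_all[intersect(degs, rownames(expr_all)), , drop = FALSE]
  if (nrow(expr_deg) < cfg$min_size)
    stop2("module detection: DEG union smaller than min module size")
  mod <- detect_modules(expr_deg, beta = cfg$beta, min_size = cfg$min_size,
                        merge_cut = cfg$merge_cut, min_kme = cfg$min_kme)
  res$modules <- mod$labels
  res$eigengenes <- mod$eigengenes
  res$module_trait <- if (!is.null(mod$eigengenes))
    module_trait_correlation(mod$eigengenes, design) else NULL

  res$pca <- pca_qc(norm)

  tfs <- intersect(data$tf_catalog$gene, rownames(expr_all))
  targets <- intersect(names(data$promoters), rownames(expr_all))
  res$motif_hits <- scan_promoters(data$pwm_library[tfs], data$promoters,
                                   p_max = cfg$motif_pmax)
  res$corr_edges <- pearson_edges(expr_all, tfs, targets,
                                  min_abs_r = cfg$min_abs_r,
                                  alpha = cfg$corr_alpha)
  allowed <- sort(unique(res$modules[res$modules > 0]))
  res$network <- assemble_regulatory_network(
    res$motif_hits, res$corr_edges, res$modules, allowed,
    data$tf_catalog, p_max = cfg$motif_pmax)
  res$hubs <- hub_ranking(res$network, data$tf_catalog)

  if (!is.null(gene_sets)) {
    res$enrichment <- hypergeom_enrich(degs, gene_sets, rownames(expr_all))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$out_dir
    write_design(design, file.path(od, "design.tsv"))
    for (tp in timepoints) {
      write_tsv(res$deg[[tp]], file.path(od, paste0("deg_", tp, ".tsv")))
      write_tsv(res$dam[[tp]], file.path(od, paste0("dam_", tp, ".tsv")))
    }
    write_tsv(data.frame(gene = names(res$modules),
                         module = unname(res$modules)),
              file.path(od, "module_labels.tsv"))
    if (!is.null(res$eigengenes))
      write_tsv(data.frame(sample_id = rownames(res$eigengenes),
                           res$eigengenes, check.names = FALSE),
                file.path(od, "eigengenes.tsv"))
    if (!is.null(res$module_trait))
      write_tsv(res$module_trait, file.path(od, "module_trait.tsv"))
    write_tsv(res$motif_hits, file.path(od, "motif_hits.tsv"))
    write_edge_table(res$network, file.path(od, "network_edges.tsv"))
    write_tsv(res$hubs$hubs, file.path(od, "hub_ranking.tsv"))
    write_tsv(res$hubs$family_tally, file.path(od, "family_tally.tsv"))
    if (!is.null(res$enrichment))
      write_tsv(res$enrichment, file.path(od, "enrichment.tsv"))
    log_cfg <- cfg
    log_cfg$module_sizes <- paste(cfg$module_sizes, collapse = ",")
    writeLines(c(paste0("uvaregnet run ", format(Sys.time())),
                 paste0(names(log_cfg), " = ",
                        vapply(log_cfg, function(v)
                          paste(format(v), collapse = ","), character(1)))),
               file.path(od, "run.log"))
  }
  res
}
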
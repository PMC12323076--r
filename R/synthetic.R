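# Synthetic multi-omics generator with planted ground truth. Emulates the
# study design the pipeline targets: 2 treatments (CK control vs UVA
# supplementation) x 4 sampling times (4h, 1d, 2d, 3d) x replicated plants,
# with planted coexpression modules whose latent profiles respond to
# treatment, planted differential metabolites, and promoters carrying planted
# PWM instances for designated TF -> target pairs.

TREATMENTS <- c("CK", "UVA")
TIMEPOINTS <- c("4h", "1d", "2d", "3d")

#' Generate the sample design table
#'
#' Two treatments (CK, UVA) by four time points (4h, 1d, 2d, 3d) by
#' `n_reps` biological replicates, in a fixed deterministic order.
#'
#' @param n_reps Replicates per treatment x time group (>= 2).
#' @param seed Unused for content (the table is deterministic) but kept in
#'   the signature so all generators share one calling convention.
#' @return A data.frame with columns sample_id, treatment, timepoint,
#'   replicate.
#' @export
generate_design <- function(n_reps = 3, seed = 1) {
  if (n_reps < 2) stop2("n_reps must be >= 2 (downstream tests need replicates)")
  d <- expand.grid(replicate = seq_len(n_reps), timepoint = TIMEPOINTS,
                   treatment = TREATMENTS, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  d <- d[, c("treatment", "timepoint", "replicate")]
  d$sample_id <- sprintf("%s_%s_r%d", d$treatment, d$timepoint, d$replicate)
  rownames(d) <- NULL
  d[, c("sample_id", "treatment", "timepoint", "replicate")]
}

# latent per-group module profile: a smooth random walk over the 4 time
# points shared by both treatments, plus a treatment shift at affected
# time points for responsive modules. With only 4 time points, independent
# walks frequently collide; each module's full treatment-x-time group
# profile (walk plus shift) is rejection-sampled to keep pairwise |cor|
# with already-accepted modules below `max_cor`, so planted modules are
# mutually distinguishable the way real modules with distinct kinetics are.
module_latent_profiles <- function(n_modules, step_sd, scale_sd,
                                   shifts = NULL, max_cor = 0.6,
                                   max_tries = 200L) {
  lat <- matrix(0, n_modules, length(TIMEPOINTS),
                dimnames = list(NULL, TIMEPOINTS))
  if (is.null(shifts)) shifts <- matrix(0, n_modules, length(TIMEPOINTS))
  group_prof <- function(walk, m) c(walk, walk + shifts[m, ])  # CK then UVA
  accepted <- NULL
  for (m in seq_len(n_modules)) {
    best <- NULL
    best_cor <- Inf
    for (try in seq_len(max_tries)) {
      walk <- cumsum(stats::rnorm(length(TIMEPOINTS), 0, step_sd))
      walk <- walk - mean(walk)
      walk <- walk * (scale_sd / max(stats::sd(walk), 1e-8))
      gp <- group_prof(walk, m)
      worst <- if (is.null(accepted)) 0 else
        max(abs(stats::cor(gp, t(accepted))))
      if (worst < best_cor) {
        best <- walk
        best_cor <- worst
      }
      if (worst <= max_cor) break
    }
    lat[m, ] <- best
    accepted <- rbind(accepted, group_prof(best, m))
  }
  lat
}

#' Generate an expression count matrix with planted coexpression modules
#'
#' Counts follow a negative-binomial model: the mean of gene g in sample s is
#' `baseline_g * 2^latent`, where genes of the same module share a smooth
#' latent time profile (a scaled random walk over the four time points) plus
#' independent per-sample noise. Modules flagged UVA-responsive shift their
#' latent by a signed `effect_log2` in UVA samples at the affected time
#' points (signs alternate across responsive modules). Background genes are
#' independent noise.
#'
#' @param design Design table from [generate_design()].
#' @param n_genes Total number of genes.
#' @param module_sizes Integer vector of planted module sizes (each >= 2).
#' @param effect_log2 Absolute treatment effect on responsive modules, in
#'   log2 units (>= 0).
#' @param dispersion Negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2` (> 0).
#' @param seed Integer seed.
#' @param responsive_modules Indices of modules that respond to UVA.
#' @param affected_timepoints Time points at which responsive modules shift.
#' @param noise_sd Per-gene, per-sample log2 noise sd around the module
#'   latent.
#' @param latent_sd Across-time sd of each module's latent profile (log2).
#' @param baseline_log2_mean,baseline_log2_sd Log2-normal baseline mean
#'   expression parameters.
#' @return `list(counts=, truth=)`; `truth` carries `module_of` (named
#'   integer vector, 0 = background), `de_genes` (gene, timepoint, effect)
#'   and the module latent profiles.
#' @export
generate_expression <- function(design, n_genes = 2000,
                                module_sizes = rep(100L, 6L),
                                effect_log2 = 2, dispersion = 0.005,
                                seed = 1,
                                responsive_modules = seq_along(module_sizes),
                                affected_timepoints = TIMEPOINTS,
                                noise_sd = 0.15, latent_sd = 1.5,
                                baseline_log2_mean = 8,
                                baseline_log2_sd = 1.2) {
  check_design(design)
  if (length(module_sizes) && any(module_sizes < 2))
    stop2("module_sizes must all be >= 2")
  if (sum(module_sizes) > n_genes) stop2("sum(module_sizes) exceeds n_genes")
  if (dispersion <= 0) stop2("dispersion must be > 0")
  if (effect_log2 < 0) stop2("effect_log2 must be >= 0")
  set.seed(seed)
  n_mod <- length(module_sizes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  module_of <- stats::setNames(integer(n_genes), genes)
  if (n_mod) {
    module_of[seq_len(sum(module_sizes))] <-
      rep(seq_len(n_mod), times = module_sizes)
  }
  effect_sign <- rep_len(c(1, -1), n_mod)
  shifts <- matrix(0, max(n_mod, 1L), length(TIMEPOINTS),
                   dimnames = list(NULL, TIMEPOINTS))
  for (m in seq_len(n_mod)) {
    if (m %in% responsive_modules)
      shifts[m, TIMEPOINTS %in% affected_timepoints] <-
        effect_sign[m] * effect_log2
  }
  latent <- module_latent_profiles(n_mod, step_sd = 0.8,
                                   scale_sd = latent_sd, shifts = shifts)
  n_s <- nrow(design)
  baseline <- 2^stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  # per-sample latent value per gene (log2 scale)
  log2mu <- matrix(0, n_genes, n_s, dimnames = list(genes, design$sample_id))
  tp_idx <- match(design$timepoint, TIMEPOINTS)
  is_uva <- design$treatment == "UVA"
  affected <- design$timepoint %in% affected_timepoints
  for (g in seq_len(n_genes)) {
    m <- module_of[g]
    prof <- if (m > 0) latent[m, tp_idx] else numeric(n_s)
    if (m > 0 && m %in% responsive_modules) {
      prof <- prof + effect_sign[m] * effect_log2 * (is_uva & affected)
    }
    log2mu[g, ] <- prof + stats::rnorm(n_s, 0, noise_sd)
  }
  mu <- baseline * 2^log2mu
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, n_s, dimnames = dimnames(mu))
  de <- which(module_of > 0 & module_of %in% responsive_modules)
  de_genes <- if (length(de) && effect_log2 > 0) {
    do.call(rbind, lapply(affected_timepoints, function(tp)
      data.frame(gene = genes[de], timepoint = tp,
                 effect = effect_sign[module_of[de]] * effect_log2,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(gene = character(), timepoint = character(),
               effect = numeric(), stringsAsFactors = FALSE)
  }
  list(counts = counts,
       truth = list(module_of = module_of, de_genes = de_genes,
                    latent = latent, effect_sign = effect_sign,
                    responsive_modules = responsive_modules,
                    affected_timepoints = affected_timepoints))
}

#' Generate a metabolite abundance matrix with planted DAMs
#'
#' Abundances are log-normal; planted differentially accumulated metabolites
#' (DAMs) are shifted by a signed log2 effect in all UVA samples. Values are
#' strictly positive.
#'
#' @param design Design table.
#' @param n_metabolites Number of metabolites.
#' @param n_dams Number of planted DAMs (<= n_metabolites).
#' @param effect_log2 Absolute log2 effect (>= 0); per-DAM signs via `signs`.
#' @param seed Integer seed.
#' @param signs Optional vector of +1/-1 per DAM (recycled); default all +1.
#' @param noise_sd Per-sample log2 noise sd.
#' @param base_log2_mean,base_log2_sd Log2 baseline intensity parameters.
#' @return `list(abundance=, truth=)`; truth$dam_metabolites is a named
#'   vector of signed log2 effects.
#' @export
generate_metabolome <- function(design, n_metabolites = 300, n_dams = 30,
                                effect_log2 = 2, seed = 1, signs = 1,
                                noise_sd = 0.35, base_log2_mean = 20,
                                base_log2_sd = 2) {
  check_design(design)
  if (n_dams > n_metabolites) stop2("n_dams must be <= n_metabolites")
  if (effect_log2 < 0)
    stop2("effect_log2 must be >= 0; encode direction via `signs`")
  set.seed(seed)
  mets <- sprintf("M%04d", seq_len(n_metabolites))
  n_s <- nrow(design)
  base <- stats::rnorm(n_metabolites, base_log2_mean, base_log2_sd)
  eff <- numeric(n_metabolites)
  if (n_dams > 0) eff[seq_len(n_dams)] <- rep_len(signs, n_dams) * effect_log2
  is_uva <- design$treatment == "UVA"
  log2ab <- matrix(stats::rnorm(n_metabolites * n_s, 0, noise_sd),
                   n_metabolites, n_s,
                   dimnames = list(mets, design$sample_id))
  log2ab <- log2ab + base + outer(eff, as.numeric(is_uva))
  dams <- stats::setNames(eff[seq_len(n_dams)], mets[seq_len(n_dams)])
  if (n_dams == 0) dams <- stats::setNames(numeric(0), character(0))
  list(abundance = 2^log2ab,
       truth = list(dam_metabolites = dams))
}

#' Generate promoter sequences with planted motif instances
#'
#' Background bases are i.i.d. with the requested GC content; at each
#' planted placement the bases are drawn column-wise from the PWM's
#' probabilities (or set to the consensus when `consensus = TRUE`).
#' Reverse-strand placements insert the reverse complement of the sampled
#' site. Overlapping placements on one gene are an error so the ground truth
#' stays unambiguous.
#'
#' @param genes Character vector of gene ids needing promoters.
#' @param pwm_library Named list of `pwm` objects.
#' @param placements data.frame with columns motif_id, gene, offset (1-based
#'   start), strand ("+" or "-"); may have zero rows.
#' @param length Promoter length in bp (default 2000, upstream of the start
#'   codon).
#' @param gc GC content of the background, in (0, 1).
#' @param seed Integer seed.
#' @param consensus Plant consensus sites instead of sampling from the PWM?
#' @return Named character vector of promoter sequences.
#' @export
generate_promoters <- function(genes, pwm_library = list(),
                               placements = NULL, length = 2000, gc = 0.4,
                               seed = 1, consensus = FALSE) {
  if (gc <= 0 || gc >= 1) stop2("gc must be in (0, 1)")
  if (is.null(placements))
    placements <- data.frame(motif_id = character(), gene = character(),
                             offset = integer(), strand = character())
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(genes, function(g)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  if (nrow(placements)) {
    widths <- vapply(as.character(placements$motif_id), function(id) {
      if (is.null(pwm_library[[id]])) stop2("placement motif '", id,
                                            "' not in pwm_library")
      pwm_library[[id]]$width
    }, integer(1))
    if (any(placements$offset < 1 | placements$offset + widths - 1 > length))
      stop2("placement outside promoter bounds")
    for (g in unique(placements$gene)) {
      pg <- placements[placements$gene == g, , drop = FALSE]
      wg <- widths[placements$gene == g]
      o <- order(pg$offset)
      ends <- pg$offset[o] + wg[o] - 1L
      if (any(pg$offset[o][-1L] <= ends[-length(ends)]))
        stop2("overlapping placements on gene ", g)
    }
    for (i in seq_len(nrow(placements))) {
      p <- pwm_library[[as.character(placements$motif_id[i])]]
      site <- if (consensus) {
        strsplit(pwm_consensus(p), "")[[1L]]
      } else {
        vapply(seq_len(p$width), function(j)
          sample(DNA_BASES, 1L, prob = p$probs[j, ]), character(1))
      }
      if (placements$strand[i] == "-")
        site <- rev(c(A = "T", C = "G", G = "C", T = "A")[site])
      g <- as.character(placements$gene[i])
      off <- placements$offset[i]
      substr(seqs[[g]], off, off + p$width - 1L) <- paste(site, collapse = "")
    }
  }
  seqs
}

#' Build a library of synthetic TF binding motifs
#'
#' Each motif has a random consensus word and concentrated columns
#' (probability `concentration` on the consensus base), giving informative
#' plant-TF-like PWMs whose planted sites pass a FIMO-style 1e-4 scan
#' threshold with high probability.
#'
#' @param ids Motif ids (one per TF).
#' @param width Motif width in bp.
#' @param concentration Probability mass on the consensus base per column.
#' @param seed Integer seed.
#' @param background Background frequencies for log-odds.
#' @return Named list of `pwm` objects.
#' @export
demo_motif_library <- function(ids, width = 12, concentration = 0.95,
                               seed = 1, background = rep(0.25, 4)) {
  set.seed(seed)
  out <- lapply(ids, function(id) {
    cons <- sample.int(4L, width, replace = TRUE)
    probs <- matrix((1 - concentration) / 3, width, 4L)
    probs[cbind(seq_len(width), cons)] <- concentration
    build_pwm(probs, background = background, id = id)
  })
  stats::setNames(out, ids)
}

#' Simulate a complete multi-omics dataset with planted regulatory truth
#'
#' Builds the full fixture every pipeline stage consumes: design, expression
#' counts with planted modules, metabolite abundances with planted DAMs, a
#' TF catalog (TFs are module genes, so the module-restricted network join is
#' exercised), a synthetic motif library, promoters for the structural target
#' genes with planted sites for each designated TF -> target edge, and the
#' ground truth needed to score recovery.
#'
#' @param seed Integer seed; all stages derive their own seeds from it.
#' @param n_genes,module_sizes,effect_log2,dispersion Passed to
#'   [generate_expression()].
#' @param n_metabolites,n_dams,met_effect_log2 Passed to
#'   [generate_metabolome()].
#' @param tfs_per_module,targets_per_module TFs and structural target genes
#'   designated inside each planted module.
#' @param promoter_length Promoter length (bp).
#' @return A list with design, counts, abundance, promoters, pwm_library,
#'   tf_catalog (data.frame gene, family), and truth (module_of, de_genes,
#'   dam_metabolites, regulatory_edges, motif_placements).
#' @export
simulate_uva_dataset <- function(seed = 1, n_genes = 2000,
                                 module_sizes = rep(100L, 6L),
                                 effect_log2 = 2, dispersion = 0.005,
                                 n_metabolites = 300, n_dams = 30,
                                 met_effect_log2 = 2,
                                 tfs_per_module = 2L,
                                 targets_per_module = 5L,
                                 promoter_length = 2000L) {
  design <- generate_design(3, derive_seed(seed, "design"))
  expr <- generate_expression(design, n_genes = n_genes,
                              module_sizes = module_sizes,
                              effect_log2 = effect_log2,
                              dispersion = dispersion,
                              seed = derive_seed(seed, "expression"))
  metab <- generate_metabolome(design, n_metabolites = n_metabolites,
                               n_dams = n_dams,
                               effect_log2 = met_effect_log2,
                               seed = derive_seed(seed, "metabolome"))
  module_of <- expr$truth$module_of
  n_mod <- length(module_sizes)
  families <- c("MYB", "WRKY", "bHLH", "bZIP", "ERF", "GATA")
  tf_catalog <- NULL
  edges <- NULL
  for (m in seq_len(n_mod)) {
    mg <- names(module_of)[module_of == m]
    tfs <- mg[seq_len(tfs_per_module)]
    targets <- mg[tfs_per_module + seq_len(targets_per_module)]
    tf_catalog <- rbind(tf_catalog, data.frame(
      gene = tfs, family = families[(seq_along(tfs) + m - 2L) %%
                                      length(families) + 1L],
      stringsAsFactors = FALSE))
    # each TF regulates a disjoint slice of the module's targets
    split_at <- ceiling(targets_per_module * seq_len(tfs_per_module) /
                          tfs_per_module)
    lo <- c(1L, utils::head(split_at, -1L) + 1L)
    for (k in seq_along(tfs)) {
      tg <- targets[seq(lo[k], split_at[k])]
      edges <- rbind(edges, data.frame(tf = tfs[k], target = tg,
                                       stringsAsFactors = FALSE))
    }
  }
  pwm_library <- demo_motif_library(tf_catalog$gene,
                                    seed = derive_seed(seed, "motifs"))
  # one planted site per regulatory edge, random non-overlapping offsets
  set.seed(derive_seed(seed, "placements"))
  placements <- do.call(rbind, lapply(split(edges, edges$target), function(e) {
    w <- vapply(e$tf, function(id) pwm_library[[id]]$width, integer(1))
    slots <- floor(promoter_length / (max(w) + 20L))
    pos <- sort(sample.int(slots, nrow(e))) * (max(w) + 20L) - max(w)
    data.frame(motif_id = e$tf, gene = e$target, offset = pos,
               strand = sample(c("+", "-"), nrow(e), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(placements) <- NULL
  # promoters for every module structural target (planted edges plus
  # same-module negatives that only lack the motif evidence)
  prom_genes <- unique(unlist(lapply(seq_len(n_mod), function(m) {
    mg <- names(module_of)[module_of == m]
    mg[tfs_per_module + seq_len(targets_per_module)]
  })))
  promoters <- generate_promoters(prom_genes, pwm_library, placements,
                                  length = promoter_length,
                                  seed = derive_seed(seed, "promoters"))
  truth <- expr$truth
  truth$dam_metabolites <- metab$truth$dam_metabolites
  truth$regulatory_edges <- edges
  truth$motif_placements <- placements
  list(design = design, counts = expr$counts, abundance = metab$abundance,
       promoters = promoters, pwm_library = pwm_library,
       tf_catalog = tf_catalog, truth = truth)
}
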
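#' Configuration for the synthetic enChIP-MS experiment
#'
#' The defaults emulate the target experimental design: three gD4Z4 guides
#' (targeting different positions of the repeat unit) and gMYOD1 control
#' pulldowns, each a singleton FLAG immunoprecipitation, plus a handful of
#' planted truth classes — locus-specific nuclear proteins (signal in gD4Z4
#' pulldowns only), shared nuclear background proteins, list-matched
#' contaminants, and abundant non-nuclear decoys. PSM counts are Poisson
#' draws with independent dropout; distinct-peptide counts are drawn between
#' 1 and the PSM count; coverage is proportional to distinct peptides,
#' capped at 100.
#'
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @param n_gd4z4_samples number of gD4Z4 FLAG pulldowns (default 3, one per
#'   guide; cycled through gD4Z4-1/2/3).
#' @param n_gmyod1_samples number of gMYOD1 FLAG pulldowns (default 2).
#' @param n_locus_proteins planted locus-specific nuclear proteins (default 8).
#' @param n_background_proteins shared nuclear background proteins
#'   (default 30).
#' @param n_contaminants planted contaminants, list-matched (default 5).
#' @param n_nonnuclear_decoys abundant cytoplasmic decoys (default 5).
#' @param lambda_signal Poisson mean PSM count for signal-like observations
#'   (default 6).
#' @param lambda_background Poisson mean for background observations — shared
#'   background proteins everywhere and locus proteins in control pulldowns
#'   (default 0.3, a sporadic nonspecific-carryover rate).
#' @param dropout_prob probability that an observation is zeroed (default
#'   0.1).
#' @param coverage_per_peptide percent coverage per distinct peptide, capped
#'   at 100 (default 3).
#' @param dispersion optional negative-binomial size parameter; NULL
#'   (default) keeps pure Poisson counts.
#' @return list of class `enchip_sim_config`.
#' @export
enchip_sim_config <- function(seed = 1L,
                              n_gd4z4_samples = 3L, n_gmyod1_samples = 2L,
                              n_locus_proteins = 8L,
                              n_background_proteins = 30L,
                              n_contaminants = 5L,
                              n_nonnuclear_decoys = 5L,
                              lambda_signal = 6, lambda_background = 0.3,
                              dropout_prob = 0.1,
                              coverage_per_peptide = 3,
                              dispersion = NULL) {
  if (lambda_signal < 0 || lambda_background < 0) {
    stop_validation("Poisson rates must be >= 0")
  }
  if (dropout_prob < 0 || dropout_prob > 1) {
    stop_validation("dropout_prob must lie in [0, 1]")
  }
  if (n_gd4z4_samples < 1 || n_gmyod1_samples < 1) {
    stop_validation("at least one sample per guide-target class required")
  }
  structure(as.list(environment()), class = "enchip_sim_config")
}

draw_counts <- function(n, lambda, cfg) {
  # rpois/rnbinom accept a rate vector; a zero rate yields an exact zero
  if (is.null(cfg$dispersion)) stats::rpois(n, lambda)
  else stats::rnbinom(n, size = cfg$dispersion, mu = lambda)
}

#' Simulate an enChIP-MS fixture bundle with known truth
#'
#' Generates a long evidence table, a design sheet, an annotation table, a
#' contaminant list and the planted truth. Locus proteins draw
#' Poisson(lambda_signal) PSM counts in gD4Z4 samples and
#' Poisson(lambda_background) in gMYOD1 samples; background proteins draw
#' Poisson(lambda_background) everywhere; contaminants and non-nuclear decoys
#' draw signal-like counts in every sample. Each observation is independently
#' zeroed with probability `dropout_prob`; zero observations are omitted from
#' the evidence table (an absent pair is an exact zero downstream).
#' Contaminants are annotated as nuclear on purpose, so that removing them
#' exercises the contaminant list rather than the nuclear filter.
#'
#' @param cfg an [enchip_sim_config()].
#' @return list with `evidence`, `design`, `annotations`, `contaminants` and
#'   `truth` (planted accession sets plus the seed).
#' @export
simulate_enchip <- function(cfg = enchip_sim_config()) {
  stopifnot(inherits(cfg, "enchip_sim_config"))
  set.seed(cfg$seed)

  design <- tibble::tibble(
    sample_id = c(sprintf("D4Z4_S%d", seq_len(cfg$n_gd4z4_samples)),
                  sprintf("MYOD1_S%d", seq_len(cfg$n_gmyod1_samples))),
    guide_id = c(sprintf("gD4Z4-%d",
                         (seq_len(cfg$n_gd4z4_samples) - 1L) %% 3L + 1L),
                 rep("gMYOD1", cfg$n_gmyod1_samples)),
    replicate_index = c(seq_len(cfg$n_gd4z4_samples),
                        seq_len(cfg$n_gmyod1_samples)),
    ip_antibody = "FLAG")
  design <- validate_design(design)

  mk <- function(prefix, n) if (n > 0) sprintf("%s%03d", prefix, seq_len(n))
                            else character(0)
  locus <- mk("LOCUS", cfg$n_locus_proteins)
  background <- mk("BG", cfg$n_background_proteins)
  contam <- mk("CONTAM", cfg$n_contaminants)
  decoy <- mk("DECOY", cfg$n_nonnuclear_decoys)
  all_acc <- c(locus, background, contam, decoy)

  grid <- expand.grid(sample_idx = seq_len(nrow(design)), acc = all_acc,
                      stringsAsFactors = FALSE)
  is_gd <- design$target_class[grid$sample_idx] == "gD4Z4"
  lambda <- ifelse(grid$acc %in% locus,
                   ifelse(is_gd, cfg$lambda_signal, cfg$lambda_background),
                   ifelse(grid$acc %in% background, cfg$lambda_background,
                          # contaminants and decoys are abundant everywhere
                          cfg$lambda_signal))
  psm <- if (nrow(grid) > 0) draw_counts(nrow(grid), lambda, cfg)
         else integer(0)
  if (cfg$dropout_prob > 0 && nrow(grid) > 0) {
    psm[stats::runif(nrow(grid)) < cfg$dropout_prob] <- 0L
  }
  keep <- psm > 0
  psm <- as.integer(psm[keep])
  # distinct peptides uniform on 1..psm, never exceeding the PSM count
  pep <- as.integer(ceiling(stats::runif(length(psm)) * psm))
  evidence <- tibble::tibble(
    protein_accession = grid$acc[keep],
    gene_symbol = paste0(grid$acc[keep], "_G"),
    sample_id = design$sample_id[grid$sample_idx[keep]],
    psm_count = psm,
    distinct_peptide_count = pep,
    percent_coverage = pmin(100, cfg$coverage_per_peptide * pep))

  annotations <- tibble::tibble(
    protein_accession = all_acc,
    gene_symbol = paste0(all_acc, "_G"),
    function_text = ifelse(all_acc %in% decoy,
                           "Glycolytic enzyme of the cytosol",
                           "Chromatin-associated regulatory factor"),
    subcellular_location = ifelse(all_acc %in% decoy,
                                  "Cytoplasm; Cytosol",
                                  "Nucleus; Chromosome"))

  list(evidence = evidence, design = design, annotations = annotations,
       contaminants = contam,
       truth = list(locus_specific = locus, background = background,
                    contaminants = contam, non_nuclear = decoy,
                    seed = cfg$seed))
}

#' Configuration for the synthetic RT-qPCR experiment
#'
#' Ct values follow `Ct = baseline - log2(relative expression) + N(0, sd)`
#' per well; reference genes are unaffected by the planted condition folds.
#' Defaults reflect a typical knockdown/induction panel read in technical
#' triplicate over three biological replicates.
#'
#' @param seed integer seed.
#' @param fold_changes named numeric vector of planted fold changes per
#'   condition; must include the control condition at fold 1.
#' @param control_condition name of the baseline condition.
#' @param n_bio_reps biological replicates per condition (default 3).
#' @param n_tech_reps technical replicates per well group (default 3).
#' @param ct_noise_sd per-well Ct noise SD in cycles (default 0.2).
#' @param target_baseline_ct control-condition target Ct (default 28).
#' @param reference_baseline_cts named vector of reference-gene baseline Cts.
#' @return list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(seed = 1L,
                            fold_changes = c(CTRL = 1, TREAT = 4),
                            control_condition = "CTRL",
                            n_bio_reps = 3L, n_tech_reps = 3L,
                            ct_noise_sd = 0.2,
                            target_baseline_ct = 28,
                            reference_baseline_cts = c(RPL27 = 18,
                                                       RPL13A = 19,
                                                       GAPDH = 20)) {
  if (any(fold_changes <= 0)) stop_validation("fold changes must be > 0")
  if (ct_noise_sd < 0) stop_validation("ct_noise_sd must be >= 0")
  if (!control_condition %in% names(fold_changes)) {
    stop_validation("fold_changes must include the control condition")
  }
  if (n_bio_reps < 1 || n_tech_reps < 1) {
    stop_validation("replicate counts must be >= 1")
  }
  structure(as.list(environment()), class = "qpcr_sim_config")
}

#' Simulate an RT-qPCR Ct table with planted fold changes
#'
#' @param cfg a [qpcr_sim_config()].
#' @param target_gene name of the simulated target gene (default "DUX4").
#' @return list with `records` (long Ct table: condition, gene, bio_rep,
#'   tech_rep, ct) and `truth` (planted fold changes relative to control,
#'   seed).
#' @export
simulate_qpcr <- function(cfg = qpcr_sim_config(), target_gene = "DUX4") {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  set.seed(cfg$seed)
  genes <- c(stats::setNames(cfg$target_baseline_ct, target_gene),
             cfg$reference_baseline_cts)
  grid <- expand.grid(tech_rep = seq_len(cfg$n_tech_reps),
                      gene = names(genes),
                      bio_rep = seq_len(cfg$n_bio_reps),
                      condition = names(cfg$fold_changes),
                      stringsAsFactors = FALSE)
  # only the target responds to the planted fold change
  shift <- ifelse(grid$gene == target_gene,
                  log2(cfg$fold_changes[grid$condition]), 0)
  noise <- if (cfg$ct_noise_sd > 0)
    stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd) else 0
  records <- tibble::tibble(
    condition = grid$condition, gene = grid$gene, bio_rep = grid$bio_rep,
    tech_rep = grid$tech_rep,
    ct = unname(genes[grid$gene] - shift + noise))
  truth_folds <- cfg$fold_changes / cfg$fold_changes[[cfg$control_condition]]
  list(records = records,
       truth = list(fold_changes = truth_folds,
                    control_condition = cfg$control_condition,
                    target_gene = target_gene, seed = cfg$seed))
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' Builds a universe of `N` genes, a query of `query_size` genes, and
#' `n_terms` terms of which the first (the planted term) shares exactly
#' `overlap` genes with the query; the remaining terms are uniform random
#' draws from the universe.
#'
#' @param seed integer seed.
#' @param N universe size.
#' @param n_terms number of terms.
#' @param planted_term_size size of the planted term.
#' @param query_size size of the query.
#' @param overlap genes shared between query and planted term
#'   (<= min(planted_term_size, query_size)).
#' @param random_term_size size of the non-planted terms (default
#'   `planted_term_size`).
#' @return list with `collection` (terms + universe, the [enrich()] input),
#'   `query`, `truth` (planted term id, overlap, seed).
#' @export
simulate_geneset_universe <- function(seed = 1L, N = 200L, n_terms = 20L,
                                      planted_term_size = 15L,
                                      query_size = 12L, overlap = 8L,
                                      random_term_size = planted_term_size) {
  if (overlap > min(planted_term_size, query_size)) {
    stop_validation("overlap cannot exceed min(planted_term_size, query_size)")
  }
  if (max(planted_term_size, query_size, random_term_size) > N) {
    stop_validation("term and query sizes cannot exceed the universe size N")
  }
  set.seed(seed)
  universe <- sprintf("GENE%04d", seq_len(N))
  shared <- sample(universe, overlap)
  query <- c(shared, sample(setdiff(universe, shared),
                            query_size - overlap))
  planted <- c(shared, sample(setdiff(universe, query),
                              planted_term_size - overlap))
  terms <- list(TERM0001 = list(term_name = "planted term", genes = planted))
  if (n_terms > 1) {
    for (i in 2:n_terms) {
      terms[[sprintf("TERM%04d", i)]] <- list(
        term_name = sprintf("random term %d", i),
        genes = sample(universe, random_term_size))
    }
  }
  list(collection = list(terms = terms, universe = universe),
       query = query,
       truth = list(planted_term = "TERM0001", overlap = overlap,
                    seed = seed))
}
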
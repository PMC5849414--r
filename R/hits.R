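#' Replicate-presence filter
#'
#' Carries a protein forward when it has at least `min_psm` peptide-spectrum
#' matches in at least `min_replicates` in-scope experimental (FLAG-IP)
#' samples. With the default `replicate_scope = "within_target_class"` the
#' detections must recur among samples sharing a guide-target class (gD4Z4 or
#' gMYOD1); with `"across_all_experimental"` any FLAG samples count.
#'
#' @param psm PSM-count matrix from [build_count_matrices()].
#' @param design design sheet.
#' @param cfg a [hit_call_config()].
#' @return character vector of retained protein accessions.
#' @export
filter_min_replicates <- function(psm, design, cfg = hit_call_config()) {
  design <- validate_design(design)
  if (length(intersect(experimental_samples(design), colnames(psm))) == 0) {
    stop_validation("replicate scope selects zero samples")
  }
  detect <- psm >= cfg$min_psm
  if (cfg$replicate_scope == "within_target_class") {
    if (nrow(psm) == 0) return(character(0))
    counts_per_class <- vapply(c("gD4Z4", "gMYOD1"), function(cl) {
      cols <- intersect(experimental_samples(design, cl), colnames(psm))
      if (length(cols) == 0) return(rep(0L, nrow(psm)))
      as.integer(rowSums(detect[, cols, drop = FALSE]))
    }, integer(nrow(psm)))
    best <- apply(matrix(counts_per_class, nrow = nrow(psm)), 1, max)
    rownames(psm)[best >= cfg$min_replicates]
  } else {
    cols <- intersect(experimental_samples(design), colnames(psm))
    if (length(cols) == 0) stop_validation("replicate scope selects zero samples")
    n_det <- rowSums(detect[, cols, drop = FALSE])
    rownames(psm)[n_det >= cfg$min_replicates]
  }
}

#' Remove common contaminants
#'
#' Drops proteins whose accession and/or gene symbol (per
#' `cfg$contaminant_match_on`) appears, case-insensitively, in a contaminant
#' list such as cRAP.
#'
#' @param proteins character vector of accessions.
#' @param contaminants character vector of contaminant identifiers (accessions
#'   or gene symbols, mixed styles allowed); see [read_contaminants()].
#' @param gene_map named character vector accession -> gene symbol (used when
#'   matching on symbols).
#' @param cfg a [hit_call_config()].
#' @return the surviving accessions, order preserved.
#' @export
filter_contaminants <- function(proteins, contaminants,
                                gene_map = character(0),
                                cfg = hit_call_config()) {
  if (length(contaminants) == 0) return(proteins)
  bad <- tolower(contaminants)
  hit <- rep(FALSE, length(proteins))
  if (cfg$contaminant_match_on %in% c("accession", "both")) {
    hit <- hit | tolower(proteins) %in% bad
  }
  if (cfg$contaminant_match_on %in% c("gene_symbol", "both")) {
    symbols <- unname(gene_map[proteins])
    hit <- hit | (!is.na(symbols) & tolower(symbols) %in% bad)
  }
  proteins[!hit]
}

#' Restrict to nuclear proteins
#'
#' Keeps a protein when any configured keyword (default: nucleus, nucleolus,
#' chromosome, nucleoplasm) occurs as a case-insensitive substring of its
#' subcellular-location or function annotation text, emulating a UniProt
#' Function / Subcellular location screen. Proteins without an annotation
#' record are dropped with a warning (or raise, per
#' `cfg$missing_annotation`).
#'
#' @param proteins character vector of accessions.
#' @param annotations data frame with columns `protein_accession`,
#'   `gene_symbol`, `function_text`, `subcellular_location` (semicolon-joined
#'   locations).
#' @param cfg a [hit_call_config()].
#' @return the surviving accessions, order preserved.
#' @export
filter_nuclear <- function(proteins, annotations, cfg = hit_call_config()) {
  assert_columns(annotations, c("protein_accession", "function_text",
                                "subcellular_location"), "annotation table")
  idx <- match(proteins, annotations$protein_accession)
  if (anyNA(idx)) {
    missing <- proteins[is.na(idx)]
    if (cfg$missing_annotation == "error") {
      stop_validation("no annotation record for: ",
                      paste(missing, collapse = ", "))
    }
    warning(length(missing), " protein(s) without annotation dropped from ",
            "the nuclear filter: ", paste(missing, collapse = ", "),
            call. = FALSE)
  }
  text <- tolower(paste(annotations$subcellular_location[idx],
                        annotations$function_text[idx]))
  pattern <- paste(cfg$nuclear_keywords, collapse = "|")
  keep <- !is.na(idx) & grepl(pattern, text, fixed = FALSE)
  proteins[keep]
}

#' Locus-specificity classification
#'
#' Flags a protein as locus-specific when it is detected (PSM count >= 1) in at
#' least `locus_min_gd4z4_samples` gD4Z4 FLAG samples while being absent from,
#' or detected in at most `control_max_replicates` of, the gMYOD1 FLAG
#' pulldowns.
#'
#' @inheritParams filter_min_replicates
#' @return named logical vector, one flag per matrix row.
#' @export
classify_locus_specific <- function(psm, design, cfg = hit_call_config()) {
  design <- validate_design(design)
  gd <- intersect(experimental_samples(design, "gD4Z4"), colnames(psm))
  gm <- intersect(experimental_samples(design, "gMYOD1"), colnames(psm))
  if (length(gd) < 2 || length(gm) < 1) {
    stop_validation("design must provide >= 2 gD4Z4 and >= 1 gMYOD1 ",
                    "FLAG samples for locus-specificity classification")
  }
  detect <- psm >= 1
  n_gd <- rowSums(detect[, gd, drop = FALSE])
  n_gm <- rowSums(detect[, gm, drop = FALSE])
  stats::setNames(n_gd >= cfg$locus_min_gd4z4_samples &
                    n_gm <= cfg$control_max_replicates,
                  rownames(psm))
}

#' Per-target-class averages (Table-style summary)
#'
#' For each protein, averages the distinct-peptide counts and percent coverage
#' over all like-class FLAG samples (gD4Z4 pulldowns combined, gMYOD1 pulldowns
#' combined), including zero-count samples in the mean. Values are returned at
#' full precision; [format_hit_table()] applies the one-decimal report
#' rounding.
#'
#' @param peptides distinct-peptide count matrix.
#' @param coverage percent-coverage matrix (same dimnames).
#' @param design design sheet.
#' @param gene_map named accession -> gene symbol vector.
#' @return tibble with one row per protein: accession, gene symbol and the
#'   four class averages.
#' @export
summarize_by_target <- function(peptides, coverage, design,
                                gene_map = character(0)) {
  design <- validate_design(design)
  stopifnot(identical(dimnames(peptides), dimnames(coverage)))
  class_mean <- function(m, cl) {
    cols <- intersect(experimental_samples(design, cl), colnames(m))
    if (length(cols) == 0) return(rep(0, nrow(m)))
    unname(rowMeans(m[, cols, drop = FALSE]))
  }
  acc <- rownames(peptides) %||% character(0)
  tibble::tibble(
    protein_accession = acc,
    gene_symbol = ifelse(is.na(gene_map[acc]), acc, unname(gene_map[acc])),
    avg_peptides_gD4Z4 = class_mean(peptides, "gD4Z4"),
    avg_coverage_gD4Z4 = class_mean(coverage, "gD4Z4"),
    avg_peptides_gMYOD1 = class_mean(peptides, "gMYOD1"),
    avg_coverage_gMYOD1 = class_mean(coverage, "gMYOD1")
  )
}

#' Run the full enChIP-MS hit-calling pipeline
#'
#' Applies, in order: the replicate-presence filter, contaminant removal,
#' nuclear restriction, locus-specificity classification, and per-target-class
#' summarization. The contaminant and nuclear filters are pure set
#' intersections, so their order does not change the result. Per-stage
#' survivor counts are recorded in the returned `stage_counts`.
#'
#' @param evidence long protein-evidence table.
#' @param design design sheet.
#' @param annotations annotation table (see [filter_nuclear()]).
#' @param contaminants contaminant identifier vector.
#' @param cfg a [hit_call_config()].
#' @return object of class `enchip_hits`: list with `hit_table` (one row per
#'   surviving protein, sorted by gene symbol then accession, with averages
#'   and flags), `stage_counts`, `cfg`.
#' @export
run_hit_pipeline <- function(evidence, design, annotations, contaminants,
                             cfg = hit_call_config()) {
  design <- validate_design(design)
  mats <- tryCatch(
    build_count_matrices(evidence, design),
    enchipms_validation_error = function(e)
      stop_validation("[count_matrices] ", conditionMessage(e)))
  all_proteins <- rownames(mats$psm)

  s1 <- filter_min_replicates(mats$psm, design, cfg)
  s2 <- filter_contaminants(s1, contaminants, mats$gene_map, cfg)
  s3 <- filter_nuclear(s2, annotations, cfg)

  locus_flag <- if (length(all_proteins) > 0)
    classify_locus_specific(mats$psm, design, cfg) else
      stats::setNames(logical(0), character(0))

  summary_tbl <- summarize_by_target(mats$peptides, mats$coverage, design,
                                     mats$gene_map)
  is_cont <- !(all_proteins %in%
                 filter_contaminants(all_proteins, contaminants,
                                     mats$gene_map, cfg))
  is_nuc <- all_proteins %in%
    suppressWarnings(filter_nuclear(all_proteins, annotations, cfg))

  tbl <- summary_tbl[summary_tbl$protein_accession %in% s3, , drop = FALSE]
  idx <- match(tbl$protein_accession, all_proteins)
  tbl$is_contaminant <- is_cont[idx]
  tbl$is_nuclear <- is_nuc[idx]
  tbl$passes_replicate_filter <- TRUE
  tbl$is_locus_specific <- unname(locus_flag[tbl$protein_accession])
  tbl <- tbl[order(tbl$gene_symbol, tbl$protein_accession), , drop = FALSE]

  structure(list(
    hit_table = tbl,
    stage_counts = c(input = length(all_proteins),
                     replicate_filter = length(s1),
                     contaminant_filter = length(s2),
                     nuclear_filter = length(s3),
                     locus_specific = sum(tbl$is_locus_specific)),
    cfg = cfg
  ), class = "enchip_hits")
}

#' Format a hit table for reporting
#'
#' Applies the one-decimal, half-away-from-zero rounding used in manuscript
#' summary tables to the class averages. Internal precision is untouched.
#'
#' @param hits an `enchip_hits` object or its `hit_table`.
#' @return tibble with rounded averages.
#' @export
format_hit_table <- function(hits) {
  tbl <- if (inherits(hits, "enchip_hits")) hits$hit_table else hits
  for (col in c("avg_peptides_gD4Z4", "avg_coverage_gD4Z4",
                "avg_peptides_gMYOD1", "avg_coverage_gMYOD1")) {
    tbl[[col]] <- round_half_up(tbl[[col]], 1)
  }
  tbl
}

#' @export
print.enchip_hits <- function(x, ...) {
  cat("enChIP-MS hit-calling result\n")
  cat("  stage survivors:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = ", "), "\n")
  cat("  locus-specific hits:", sum(x$hit_table$is_locus_specific), "of",
      nrow(x$hit_table), "reported proteins\n")
  invisible(x)
}

#' Extract the locus-specific hit set
#'
#' @param hits an `enchip_hits` object.
#' @return character vector of accessions flagged locus-specific.
#' @export
locus_specific_hits <- function(hits) {
  tbl <- hits$hit_table
  tbl$protein_accession[tbl$is_locus_specific]
}
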
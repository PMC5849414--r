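#' Hit-calling configuration
#'
#' Parameters controlling the enChIP-MS downstream filters. The defaults
#' encode the usual presence/absence screen: a protein must show at least one
#' peptide-spectrum match (PSM) in two or more experimental replicates; it is
#' called
#' locus-specific when detected in at least two gD4Z4 pulldowns while absent
#' from, or present in at most one replicate of, the gMYOD1 control pulldowns;
#' contaminants are removed by list and the analysis is restricted to nuclear
#' proteins via annotation keywords.
#'
#' @param min_psm minimum PSM count for a sample to count as a detection
#'   (default 1).
#' @param min_replicates number of in-scope detections required to carry a
#'   protein forward (default 2).
#' @param replicate_scope `"within_target_class"` (detections must recur among
#'   samples of the same guide-target class) or `"across_all_experimental"`
#'   (any FLAG-IP samples). Either reading is defensible; the
#'   default requires recurrence within a class.
#' @param locus_min_gd4z4_samples minimum number of gD4Z4 samples with a
#'   detection for the locus-specific call (default 2, i.e. "more than one").
#' @param control_max_replicates maximum number of gMYOD1 samples with a
#'   detection still compatible with a locus-specific call (default 1).
#' @param contaminant_match_on match contaminant identifiers against
#'   `"accession"`, `"gene_symbol"` or `"both"` (default; lists mix styles).
#' @param nuclear_keywords case-insensitive substrings searched in the
#'   subcellular-location and function annotation text.
#' @param missing_annotation one of `"drop"` (default; unannotated proteins are
#'   removed from the nuclear set with a warning) or `"error"`.
#' @return a list of class `hit_call_config`.
#' @export
hit_call_config <- function(min_psm = 1L,
                            min_replicates = 2L,
                            replicate_scope = c("within_target_class",
                                                "across_all_experimental"),
                            locus_min_gd4z4_samples = 2L,
                            control_max_replicates = 1L,
                            contaminant_match_on = c("both", "accession",
                                                     "gene_symbol"),
                            nuclear_keywords = c("nucleus", "nucleolus",
                                                 "chromosome", "nucleoplasm"),
                            missing_annotation = c("drop", "error")) {
  replicate_scope <- match.arg(replicate_scope)
  contaminant_match_on <- match.arg(contaminant_match_on)
  missing_annotation <- match.arg(missing_annotation)
  for (v in c(min_psm = min_psm, min_replicates = min_replicates,
              locus_min_gd4z4_samples = locus_min_gd4z4_samples,
              control_max_replicates = control_max_replicates)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != as.integer(v)) {
      stop_validation("hit_call_config integer thresholds must be single ",
                      "non-negative integers")
    }
  }
  if (min_psm < 1) stop_validation("min_psm must be >= 1")
  if (min_replicates < 1) stop_validation("min_replicates must be >= 1")
  if (length(nuclear_keywords) == 0) {
    stop_validation("nuclear_keywords must be non-empty")
  }
  structure(list(
    min_psm = as.integer(min_psm),
    min_replicates = as.integer(min_replicates),
    replicate_scope = replicate_scope,
    locus_min_gd4z4_samples = as.integer(locus_min_gd4z4_samples),
    control_max_replicates = as.integer(control_max_replicates),
    contaminant_match_on = contaminant_match_on,
    nuclear_keywords = tolower(nuclear_keywords),
    missing_annotation = missing_annotation
  ), class = "hit_call_config")
}

#' Validate an experimental design sheet
#'
#' A design ties each sample to its guide (gD4Z4-1/2/3 or gMYOD1), derives the
#' guide-target class, and records the replicate index and IP antibody.
#'
#' @param design data frame with columns `sample_id`, `guide_id`,
#'   `replicate_index`, `ip_antibody` (FLAG or IgG).
#' @return the design as a tibble with a derived `target_class` column.
#' @export
validate_design <- function(design) {
  assert_columns(design, c("sample_id", "guide_id", "replicate_index",
                           "ip_antibody"), "design sheet")
  design <- tibble::as_tibble(design)
  if (anyDuplicated(design$sample_id)) {
    stop_validation("design sample_id values must be unique")
  }
  known <- c("gD4Z4-1", "gD4Z4-2", "gD4Z4-3", "gMYOD1")
  bad <- setdiff(unique(design$guide_id), known)
  if (length(bad) > 0) {
    stop_validation("unknown guide_id: ", paste(bad, collapse = ", "))
  }
  if (any(design$replicate_index < 1)) {
    stop_validation("replicate_index must be >= 1")
  }
  bad_ab <- setdiff(unique(design$ip_antibody), c("FLAG", "IgG"))
  if (length(bad_ab) > 0) {
    stop_validation("ip_antibody must be FLAG or IgG, got: ",
                    paste(bad_ab, collapse = ", "))
  }
  design$target_class <- ifelse(startsWith(design$guide_id, "gD4Z4"),
                                "gD4Z4", "gMYOD1")
  design
}

# FLAG-IP samples are the experimental replicates; IgG/mock never count.
experimental_samples <- function(design, target_class = NULL) {
  keep <- design$ip_antibody == "FLAG"
  if (!is.null(target_class)) keep <- keep & design$target_class == target_class
  design$sample_id[keep]
}
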
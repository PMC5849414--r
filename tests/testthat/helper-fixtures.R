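# Small in-code fixtures shared across test files.

fixture_design <- function(n_gd = 3, n_gm = 2, igg = FALSE) {
  d <- tibble::tibble(
    sample_id = c(sprintf("D%d", seq_len(n_gd)), sprintf("M%d", seq_len(n_gm))),
    guide_id = c(sprintf("gD4Z4-%d", (seq_len(n_gd) - 1) %% 3 + 1),
                 rep("gMYOD1", n_gm)),
    replicate_index = c(seq_len(n_gd), seq_len(n_gm)),
    ip_antibody = "FLAG")
  if (igg) {
    d <- rbind(d, tibble::tibble(sample_id = "IGG1", guide_id = "gD4Z4-1",
                                 replicate_index = 1, ip_antibody = "IgG"))
  }
  d
}

fixture_evidence <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(tibble::tibble(protein_accession = character(0),
                          gene_symbol = character(0),
                          sample_id = character(0), psm_count = integer(0),
                          distinct_peptide_count = integer(0),
                          percent_coverage = numeric(0)))
  }
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(protein_accession = r[[1]], gene_symbol = r[[2]],
                   sample_id = r[[3]], psm_count = as.integer(r[[4]]),
                   distinct_peptide_count = as.integer(r[[5]]),
                   percent_coverage = as.numeric(r[[6]]))
  }))
}

# PSM matrix straight from a base matrix with sample columns.
fixture_psm <- function(m, design) {
  colnames(m) <- design$sample_id[seq_len(ncol(m))]
  if (is.null(rownames(m))) rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  m
}

fixture_annotations <- function(accessions, nuclear) {
  tibble::tibble(
    protein_accession = accessions,
    gene_symbol = paste0(accessions, "_G"),
    function_text = ifelse(nuclear, "Regulates transcription",
                           "Cytosolic metabolic enzyme"),
    subcellular_location = ifelse(nuclear, "Nucleus", "Cytoplasm; Membrane"))
}
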
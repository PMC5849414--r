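#' Build protein-by-sample count matrices from an evidence table
#'
#' Pivots a long protein-evidence table (one row per protein observation per
#' sample) into three aligned matrices: PSM counts, distinct-peptide counts and
#' percent sequence coverage. Rows are protein accessions, columns are every
#' sample in the design (samples without evidence get all-zero columns), and
#' absent (protein, sample) pairs are exactly 0. Duplicate evidence rows for
#' the same (protein, sample) are summed for the two count variants and
#' maximum-taken for coverage.
#'
#' The PSM matrix is the substrate of the pseudoquant presence/absence filters;
#' the peptide and coverage matrices feed the per-target-class report.
#'
#' @param evidence data frame with columns `protein_accession`, `gene_symbol`,
#'   `sample_id`, `psm_count`, `distinct_peptide_count`, `percent_coverage`.
#' @param design a design sheet (see [validate_design()]).
#' @return list with elements `psm`, `peptides`, `coverage` (matrices sharing
#'   dimnames), and `gene_map` (named character vector accession -> symbol).
#' @export
build_count_matrices <- function(evidence, design) {
  design <- validate_design(design)
  assert_columns(evidence, c("protein_accession", "gene_symbol", "sample_id",
                             "psm_count", "distinct_peptide_count",
                             "percent_coverage"), "evidence table")
  evidence <- tibble::as_tibble(evidence)

  unknown <- setdiff(unique(evidence$sample_id), design$sample_id)
  if (length(unknown) > 0) {
    stop_validation("evidence references sample(s) absent from the design: ",
                    paste(unknown, collapse = ", "))
  }
  if (nrow(evidence) > 0 &&
      (any(evidence$psm_count < 0) || any(evidence$distinct_peptide_count < 0) ||
       any(evidence$percent_coverage < 0))) {
    stop_validation("evidence counts and coverage must be non-negative")
  }
  if (any(evidence$distinct_peptide_count > evidence$psm_count)) {
    stop_validation("distinct_peptide_count cannot exceed psm_count")
  }

  samples <- design$sample_id
  proteins <- sort(unique(evidence$protein_accession))
  empty <- function() {
    matrix(0, nrow = length(proteins), ncol = length(samples),
           dimnames = list(proteins, samples))
  }
  psm <- peptides <- coverage <- empty()
  if (nrow(evidence) > 0) {
    i <- match(evidence$protein_accession, proteins)
    j <- match(evidence$sample_id, samples)
    ij <- cbind(i, j)
    # duplicates: sum counts, max coverage
    for (r in seq_len(nrow(evidence))) {
      psm[ij[r, , drop = FALSE]] <- psm[ij[r, , drop = FALSE]] +
        evidence$psm_count[r]
      peptides[ij[r, , drop = FALSE]] <- peptides[ij[r, , drop = FALSE]] +
        evidence$distinct_peptide_count[r]
      coverage[ij[r, , drop = FALSE]] <- max(coverage[ij[r, , drop = FALSE]],
                                             evidence$percent_coverage[r])
    }
  }
  gene_map <- character(0)
  if (nrow(evidence) > 0) {
    first <- !duplicated(evidence$protein_accession)
    gene_map <- stats::setNames(evidence$gene_symbol[first],
                                evidence$protein_accession[first])
    gene_map <- gene_map[proteins]
  }
  list(psm = psm, peptides = peptides, coverage = coverage,
       gene_map = gene_map)
}
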
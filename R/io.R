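check_readable <- function(path) {
  if (!file.exists(path)) stop_io("cannot read file: ", path)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  check_readable(path)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a protein-evidence table
#'
#' Tab-separated with header. Default column names `accession`, `gene`,
#' `sample`, `psm_count`, `peptide_count`, `percent_coverage` can be remapped
#' via `col_map` (internal name -> file column name).
#'
#' @param path TSV file path.
#' @param col_map optional named character vector overriding file column
#'   names.
#' @return evidence tibble in the internal layout (see
#'   [build_count_matrices()]).
#' @export
read_evidence <- function(path, col_map = NULL) {
  defaults <- c(protein_accession = "accession", gene_symbol = "gene",
                sample_id = "sample", psm_count = "psm_count",
                distinct_peptide_count = "peptide_count",
                percent_coverage = "percent_coverage")
  if (!is.null(col_map)) defaults[names(col_map)] <- col_map
  df <- read_tsv_quiet(path)
  assert_columns(df, unname(defaults), paste0("evidence file ", path))
  out <- df[, unname(defaults)]
  names(out) <- names(defaults)
  out
}

#' Read a sample-design sheet
#'
#' TSV columns: `sample`, `guide`, `replicate`, `antibody`.
#'
#' @param path TSV file path.
#' @return validated design tibble (see [validate_design()]).
#' @export
read_design <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("sample", "guide", "replicate", "antibody"),
                 paste0("design file ", path))
  validate_design(tibble::tibble(sample_id = df$sample, guide_id = df$guide,
                                 replicate_index = df$replicate,
                                 ip_antibody = df$antibody))
}

#' Read a contaminant list
#'
#' Accepts a plain list (one identifier per line, `#` comments allowed) or a
#' cRAP-style FASTA: identifiers are taken from headers as the token after
#' the last `|`, falling back to the first whitespace-delimited word.
#'
#' @param path file path.
#' @return character vector of contaminant identifiers.
#' @export
read_contaminants <- function(path) {
  check_readable(path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(character(0))
  if (any(startsWith(lines, ">"))) {
    headers <- sub("^>", "", lines[startsWith(lines, ">")])
    first_word <- sub("\\s.*$", "", headers)
    ids <- vapply(first_word, function(w) {
      parts <- strsplit(w, "|", fixed = TRUE)[[1]]
      parts[length(parts)]
    }, character(1), USE.NAMES = FALSE)
    unique(ids)
  } else {
    unique(lines)
  }
}

#' Read a UniProt-style annotation table
#'
#' TSV columns: `accession`, `gene`, `function`, `subcellular_location`
#' (semicolon-delimited locations).
#'
#' @param path TSV file path.
#' @return annotation tibble for [filter_nuclear()].
#' @export
read_annotations <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("accession", "gene", "function",
                       "subcellular_location"),
                 paste0("annotation file ", path))
  if (anyDuplicated(df$accession)) {
    stop_validation("annotation accessions must be unique in ", path)
  }
  tibble::tibble(protein_accession = df$accession, gene_symbol = df$gene,
                 function_text = df[["function"]],
                 subcellular_location = df$subcellular_location)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: tab-separated `term_id`, `term_name`, then member genes.
#'
#' @param path GMT file path.
#' @param universe character vector of background gene symbols (or a file
#'   path with one symbol per line).
#' @return collection list (`terms`, `universe`) consumed by [enrich()].
#' @export
read_gmt <- function(path, universe) {
  check_readable(path)
  if (length(universe) == 1 && file.exists(universe)) {
    universe <- read_universe(universe)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_validation("malformed GMT line (need id, name, >=1 gene): ",
                      substr(line, 1, 50))
    }
    if (parts[1] %in% names(terms)) {
      stop_validation("duplicate GMT term_id: ", parts[1])
    }
    terms[[parts[1]]] <- list(term_name = parts[2],
                              genes = parts[-(1:2)])
  }
  list(terms = terms, universe = universe)
}

#' Read a background-universe gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_universe <- function(path) {
  check_readable(path)
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines)])
}

#' Read a long-format qPCR Ct table
#'
#' CSV with header `condition`, `gene`, `bio_rep`, `tech_rep`, `ct`; the
#' strings `NA`, `Undetermined` and an empty field mark undetected wells.
#'
#' @param path CSV file path.
#' @return Ct records tibble for [collapse_technical()].
#' @export
read_ct_table <- function(path) {
  check_readable(path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA", "Undetermined"))
  assert_columns(df, c("condition", "gene", "bio_rep", "tech_rep", "ct"),
                 paste0("Ct file ", path))
  df$ct <- suppressWarnings(as.numeric(df$ct))
  df
}

#' Read a ChIP-qPCR table
#'
#' CSV with header `site`, `antibody`, `bio_rep`, `ct_ip`, `ct_input`,
#' `input_fraction`.
#'
#' @param path CSV file path.
#' @return tibble for [chip_percent_input()].
#' @export
read_chip_table <- function(path) {
  check_readable(path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("site", "antibody", "bio_rep", "ct_ip", "ct_input",
                       "input_fraction"), paste0("ChIP file ", path))
  df
}

#' Write the formatted hit table
#'
#' UTF-8 TSV with header; class averages carry the one-decimal report
#' rounding of [format_hit_table()].
#'
#' @param hits an `enchip_hits` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(format_hit_table(hits), path, progress = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records inputs, parameters, per-stage survivor counts, package version and
#' seed for reproducibility audits.
#'
#' @param hits an `enchip_hits` object.
#' @param path output JSON path.
#' @param inputs optional named list/vector of input descriptions.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(hits, path, inputs = NULL, seed = NULL) {
  summary <- list(
    package = "enchipms",
    version = as.character(utils::packageVersion("enchipms")),
    parameters = unclass(hits$cfg),
    stage_counts = as.list(hits$stage_counts),
    inputs = inputs,
    seed = seed
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write a synthetic fixture bundle to disk
#'
#' Serializes the output of [simulate_enchip()] (and optionally
#' [simulate_qpcr()] / [simulate_geneset_universe()]) in the formats the
#' package readers consume: evidence/design/annotation TSVs, a plain
#' contaminant list, a GMT plus universe list, a Ct CSV and a truth JSON.
#'
#' @param dir output directory (created if needed).
#' @param enchip result of [simulate_enchip()], or NULL to skip.
#' @param qpcr result of [simulate_qpcr()], or NULL to skip.
#' @param genesets result of [simulate_geneset_universe()], or NULL to skip.
#' @return named character vector of written paths, invisibly.
#' @export
write_sim_bundle <- function(dir, enchip = NULL, qpcr = NULL,
                             genesets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  truth <- list()
  p <- function(f) file.path(dir, f)
  if (!is.null(enchip)) {
    ev <- enchip$evidence
    readr::write_tsv(tibble::tibble(
      accession = ev$protein_accession, gene = ev$gene_symbol,
      sample = ev$sample_id, psm_count = ev$psm_count,
      peptide_count = ev$distinct_peptide_count,
      percent_coverage = ev$percent_coverage), p("evidence.tsv"),
      progress = FALSE)
    readr::write_tsv(tibble::tibble(
      sample = enchip$design$sample_id, guide = enchip$design$guide_id,
      replicate = enchip$design$replicate_index,
      antibody = enchip$design$ip_antibody), p("design.tsv"),
      progress = FALSE)
    an <- enchip$annotations
    readr::write_tsv(tibble::tibble(
      accession = an$protein_accession, gene = an$gene_symbol,
      "function" = an$function_text,
      subcellular_location = an$subcellular_location),
      p("annotations.tsv"), progress = FALSE)
    writeLines(enchip$contaminants, p("contaminants.txt"))
    truth$enchip <- enchip$truth
    paths <- c(paths, evidence = p("evidence.tsv"), design = p("design.tsv"),
               annotations = p("annotations.tsv"),
               contaminants = p("contaminants.txt"))
  }
  if (!is.null(qpcr)) {
    readr::write_csv(qpcr$records, p("ct_table.csv"), progress = FALSE)
    truth$qpcr <- qpcr$truth
    paths <- c(paths, ct_table = p("ct_table.csv"))
  }
  if (!is.null(genesets)) {
    gmt_lines <- vapply(names(genesets$collection$terms), function(id) {
      t <- genesets$collection$terms[[id]]
      paste(c(id, t$term_name, t$genes), collapse = "\t")
    }, character(1))
    writeLines(gmt_lines, p("genesets.gmt"))
    writeLines(genesets$collection$universe, p("universe.txt"))
    writeLines(genesets$query, p("query.txt"))
    truth$genesets <- genesets$truth
    paths <- c(paths, gmt = p("genesets.gmt"), universe = p("universe.txt"),
               query = p("query.txt"))
  }
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, truth = p("truth.json"))
  invisible(paths)
}
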
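test_that("replicate filter removes all-zero and single-replicate proteins", {
  design <- fixture_design(n_gd = 3, n_gm = 0)
  psm <- fixture_psm(rbind(P1 = c(0, 0, 0), P2 = c(5, 0, 0),
                           P3 = c(1, 1, 0)), design)
  kept <- filter_min_replicates(psm, design, hit_call_config())
  expect_setequal(kept, "P3")
})

test_that("replicate filter matches a brute-force per-row oracle", {
  set.seed(42)
  design <- fixture_design(n_gd = 3, n_gm = 3)
  psm <- fixture_psm(matrix(rpois(50 * 6, 1), nrow = 50), design)
  for (min_psm in c(1L, 2L)) {
    cfg <- hit_call_config(min_psm = min_psm,
                           replicate_scope = "across_all_experimental")
    kept <- filter_min_replicates(psm, design, cfg)
    n_det <- oracle_detect_count(psm, design$sample_id, min_psm)
    expect_setequal(kept, rownames(psm)[n_det >= 2])

    cfg_w <- hit_call_config(min_psm = min_psm)
    kept_w <- filter_min_replicates(psm, design, cfg_w)
    n_gd <- oracle_detect_count(psm, design$sample_id[1:3], min_psm)
    n_gm <- oracle_detect_count(psm, design$sample_id[4:6], min_psm)
    expect_setequal(kept_w, rownames(psm)[pmax(n_gd, n_gm) >= 2])
  }
})

test_that("raising min_psm or min_replicates never grows the retained set", {
  set.seed(7)
  design <- fixture_design(n_gd = 3, n_gm = 2)
  psm <- fixture_psm(matrix(rpois(40 * 5, 2), nrow = 40), design)
  prev <- rownames(psm)
  for (mr in 1:4) {
    kept <- filter_min_replicates(psm, design,
                                  hit_call_config(min_replicates = mr))
    expect_true(all(kept %in% prev))
    prev <- kept
  }
  k1 <- filter_min_replicates(psm, design, hit_call_config(min_psm = 1))
  k3 <- filter_min_replicates(psm, design, hit_call_config(min_psm = 3))
  expect_true(all(k3 %in% k1))
})

test_that("IgG samples never count as experimental replicates", {
  design <- fixture_design(n_gd = 2, n_gm = 1, igg = TRUE)
  psm <- fixture_psm(rbind(P1 = c(5, 0, 0, 9)), design)  # IgG-only recurrence
  expect_length(filter_min_replicates(psm, design), 0)
})

test_that("an empty sample scope is a configuration error", {
  design <- fixture_design(n_gd = 1, n_gm = 1)
  design$ip_antibody <- "IgG"
  psm <- fixture_psm(rbind(P1 = c(1, 1)), design)
  expect_error(filter_min_replicates(psm, design), "zero samples")
})

test_that("contaminant filter handles membership, no-op and mixed keys", {
  expect_setequal(filter_contaminants(c("P02533", "Q99999"), "p02533"),
                  "Q99999")
  expect_identical(filter_contaminants(c("A", "B"), character(0)),
                   c("A", "B"))
  # 10-protein fixture, mixed accession/symbol list, hand-enumerated survivors
  acc <- sprintf("ACC%02d", 1:10)
  gene_map <- stats::setNames(sprintf("GENE%02d", 1:10), acc)
  contams <- c("acc03", "GENE07", "gene10", "ACC05")
  expect_setequal(
    filter_contaminants(acc, contams, gene_map, hit_call_config()),
    c("ACC01", "ACC02", "ACC04", "ACC06", "ACC08", "ACC09"))
  # accession-only matching ignores symbol entries
  expect_setequal(
    filter_contaminants(acc, contams, gene_map,
                        hit_call_config(contaminant_match_on = "accession")),
    setdiff(acc, c("ACC03", "ACC05")))
})

test_that("nuclear filter matches a hand-labeled 12-protein fixture", {
  acc <- sprintf("P%02d", 1:12)
  ann <- tibble::tibble(
    protein_accession = acc,
    gene_symbol = acc,
    function_text = c("DNA repair in the nucleoplasm",  # kept via function
                      rep("Metabolic enzyme", 11)),
    subcellular_location = c(
      "Cytoplasm",                       # P01 kept by function text
      "Nucleus",                         # P02 kept
      "Cytoplasm; Nucleolus",            # P03 kept
      "Chromosome, centromere",          # P04 kept
      "Cytoplasm",                       # P05 dropped
      "Membrane",                        # P06 dropped
      "NUCLEUS; cytosol",                # P07 kept (case-insensitive)
      "Mitochondrion",                   # P08 dropped
      "Endoplasmic reticulum",           # P09 dropped
      "Nucleoplasm",                     # P10 kept
      "Secreted",                        # P11 dropped
      "Golgi apparatus"))                # P12 dropped
  kept <- filter_nuclear(acc, ann)
  expect_setequal(kept, c("P01", "P02", "P03", "P04", "P07", "P10"))
})

test_that("missing annotations drop with a warning or raise per policy", {
  ann <- fixture_annotations("P01", nuclear = TRUE)
  expect_warning(kept <- filter_nuclear(c("P01", "P99"), ann), "P99")
  expect_setequal(kept, "P01")
  expect_error(
    filter_nuclear(c("P01", "P99"), ann,
                   hit_call_config(missing_annotation = "error")),
    "P99")
})

test_that("contaminant and nuclear filters commute as set intersections", {
  set.seed(9)
  for (rep in 1:10) {
    acc <- sprintf("P%02d", 1:20)
    ann <- fixture_annotations(acc, nuclear = runif(20) < 0.5)
    contams <- sample(acc, 5)
    gene_map <- stats::setNames(ann$gene_symbol, acc)
    a <- filter_nuclear(filter_contaminants(acc, contams, gene_map), ann)
    b <- filter_contaminants(filter_nuclear(acc, ann), contams, gene_map)
    expect_identical(a, b)
  }
})

test_that("locus-specificity matches the exhaustive presence-pattern oracle", {
  design <- fixture_design(n_gd = 3, n_gm = 2)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  psm <- fixture_psm(patterns, design)
  flags <- classify_locus_specific(psm, design)
  for (i in seq_len(nrow(patterns))) {
    expected <- sum(patterns[i, 1:3]) >= 2 && sum(patterns[i, 4:5]) <= 1
    expect_identical(unname(flags[i]), expected)
  }
})

test_that("locus-specificity examples behave as published", {
  design <- fixture_design(n_gd = 3, n_gm = 2)
  # detected in 2 of 3 gD4Z4 samples, absent from all controls (the pattern
  # behind rows whose control averages are 0.0)
  psm <- fixture_psm(rbind(CBX3 = c(3, 2, 0, 0, 0),
                           UBIQ = c(4, 4, 4, 2, 3)), design)
  flags <- classify_locus_specific(psm, design)
  expect_true(flags[["CBX3"]])
  expect_false(flags[["UBIQ"]])  # present in every control replicate
  bad_design <- fixture_design(n_gd = 1, n_gm = 1)
  expect_error(
    classify_locus_specific(fixture_psm(rbind(P = c(1, 1)), bad_design),
                            bad_design),
    "gD4Z4")
})

test_that("class averages include zero samples and round half away from zero", {
  design <- fixture_design(n_gd = 3, n_gm = 2)
  pep <- fixture_psm(rbind(P1 = c(2, 3, 2, 0, 0),
                           P2 = c(4, 4, 4, 1, 3),
                           P3 = c(0, 0, 0, 0, 0)), design)
  cov <- pep * 2.5
  s <- summarize_by_target(pep, cov, design)
  expect_equal(s$avg_peptides_gD4Z4[s$protein_accession == "P1"], 7 / 3)
  expect_equal(round_half_up(7 / 3, 1), 2.3)
  expect_equal(s$avg_peptides_gMYOD1[s$protein_accession == "P1"], 0)
  expect_equal(s$avg_peptides_gD4Z4[s$protein_accession == "P2"], 4)
  expect_equal(s$avg_peptides_gD4Z4[s$protein_accession == "P3"], 0)
  expect_equal(s$avg_coverage_gMYOD1[s$protein_accession == "P2"], 5)
})

test_that("report rounding is half-away-from-zero at one decimal", {
  expect_equal(round_half_up(c(2.35, 2.34, -2.35, 0.05), 1),
               c(2.4, 2.3, -2.4, 0.1))
  # R's default banker's rounding would give 2.4 for 2.25 * 10 = 22.5 -> 22
  expect_equal(round_half_up(2.25, 1), 2.3)
})
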
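Package: enchipms
Title: Locus-Specific Chromatin Proteomics Hit Calling and qPCR Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of engineered DNA-binding molecule-mediated
    chromatin immunoprecipitation followed by mass spectrometry (enChIP-MS):
    spectral-count (PSM) matrix construction and pseudoquant summarization,
    replicate-presence filtering, contaminant removal, nuclear restriction and
    locus-specificity classification of candidate locus-bound proteins, with a
    local hypergeometric overrepresentation test (Bonferroni-corrected) for
    gene-set analysis, delta-delta-Ct relative quantification of RT-qPCR data,
    ChIP-qPCR percent-input enrichment, amplification-efficiency checking, and
    an exact (enumeration-based) two-tailed two-sample Mann-Whitney U test for
    small replicate numbers. Includes seeded synthetic-data generators with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
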
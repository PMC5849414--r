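#!/usr/bin/env Rscript
# Runs the enChIP-MS hit-calling pipeline on the simulated bundle:
# replicate-presence filter, contaminant removal, nuclear restriction,
# locus-specificity classification and per-target-class averaging.

suppressPackageStartupMessages(library(enchipms))

simdir <- "results/sim"
evidence <- read_evidence(file.path(simdir, "evidence.tsv"))
design <- read_design(file.path(simdir, "design.tsv"))
annotations <- read_annotations(file.path(simdir, "annotations.tsv"))
contaminants <- read_contaminants(file.path(simdir, "contaminants.txt"))
truth <- jsonlite::read_json(file.path(simdir, "truth.json"),
                             simplifyVector = TRUE)

res <- run_hit_pipeline(evidence, design, annotations, contaminants)
print(res)

write_hit_table(res, "results/hit_table.tsv")
write_run_summary(res, "results/hit_run_summary.json",
                  inputs = list(simdir = simdir), seed = truth$enchip$seed)

called <- locus_specific_hits(res)
planted <- truth$enchip$locus_specific
cat("\nLocus-specific calls:", length(called), "| planted:", length(planted),
    "| recovered:", length(intersect(called, planted)), "\n")
cat("Note: under background signal and dropout some shared background",
    "proteins can mimic the locus-specific detection pattern; the noiseless",
    "configuration (see tests) recovers the planted set exactly.\n")
cat("Hit table written to results/hit_table.tsv\n")
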
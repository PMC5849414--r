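#!/usr/bin/env Rscript
# Generates the synthetic study bundle every downstream driver consumes:
# an enChIP-MS evidence/design/annotation/contaminant set shaped like the
# three-gD4Z4-guides-vs-gMYOD1 design, a gene-set collection with one
# planted enriched term, and an RT-qPCR Ct table with planted fold changes.

suppressPackageStartupMessages(library(enchipms))

seed <- 20L
outdir <- "results/sim"

enchip <- simulate_enchip(enchip_sim_config(seed = seed))
qpcr <- simulate_qpcr(qpcr_sim_config(
  seed = seed, ct_noise_sd = 0.2,
  fold_changes = c(CTRL = 1, siCHD4 = 6, siMBD2 = 12)))
genesets <- simulate_geneset_universe(seed = seed, N = 200, n_terms = 20,
                                      planted_term_size = 15,
                                      query_size = 12, overlap = 8)

paths <- write_sim_bundle(outdir, enchip = enchip, qpcr = qpcr,
                          genesets = genesets)

cat("Simulated enChIP-MS experiment:", nrow(enchip$evidence),
    "evidence rows over", nrow(enchip$design), "FLAG pulldowns\n")
cat("  planted locus-specific nuclear proteins:",
    length(enchip$truth$locus_specific), "\n")
cat("  planted contaminants:", length(enchip$truth$contaminants),
    "| non-nuclear decoys:", length(enchip$truth$non_nuclear), "\n")
cat("Simulated qPCR panel:", nrow(qpcr$records), "wells, planted folds",
    paste(names(qpcr$truth$fold_changes), qpcr$truth$fold_changes,
          sep = "=", collapse = ", "), "\n")
cat("Gene-set collection:", length(genesets$collection$terms),
    "terms over a", length(genesets$collection$universe),
    "gene universe; planted term", genesets$truth$planted_term,
    "overlaps the query by", genesets$truth$overlap, "genes\n")
cat("Bundle written to", outdir, "(", length(paths), "files )\n")
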
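---
title: "Locus-specific chromatin proteomics hit calling and qPCR statistics: methods"
author: "enchipms authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-specific chromatin proteomics hit calling and qPCR statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enchipms)
```

## Scientific setting

Engineered DNA-binding molecule-mediated chromatin immunoprecipitation
(enChIP) purifies a single genomic locus together with its bound proteins: a
FLAG-tagged, nuclease-dead Cas9 is targeted by guide RNAs to the locus of
interest, crosslinked chromatin is immunoprecipitated with an anti-FLAG
antibody, and the co-purified proteins are identified by mass spectrometry.
`enchipms` implements the downstream half of such an experiment for a design
in which several guides target a repeat locus (the D4Z4 macrosatellite, whose
de-repression causes facioscapulohumeral muscular dystrophy) and a separate
guide targets an unrelated control locus (the MYOD1 distal regulatory
region). Everything upstream of the peptide-spectrum-match (PSM) table — raw
spectra, the database search, protein inference — is out of scope; the
pipeline starts from the per-(protein, sample) spectral-count export.

The same study design carries a set of small-sample statistics used
throughout the accompanying figures: hypergeometric overrepresentation of
gene-set annotations, delta-delta-Ct relative quantification of RT-qPCR,
ChIP-qPCR percent-input enrichment, and an exact two-tailed two-sample
Mann-Whitney U test at three biological replicates per group. All of these
are implemented here as well, each against an independent oracle in the test
suite.

## The hit-calling model

Spectral counting treats the number of PSMs assigned to a protein in a
sample as a semi-quantitative abundance proxy ("pseudoquant"). The pipeline
works on three aligned protein-by-sample matrices (PSM counts,
distinct-peptide counts, percent sequence coverage) and applies four rules
in sequence:

1. **Replicate presence.** A protein is carried forward only if it has at
   least `min_psm` (default 1) PSMs in at least `min_replicates` (default 2)
   experimental FLAG-IP samples. IgG/mock pulldowns never count. A
   two-replicate recurrence requirement does not by itself say whether
   those replicates must share a guide-target class; `replicate_scope`
   exposes both readings and defaults to `within_target_class`, the stricter
   one — a gD4Z4 candidate must recur among gD4Z4 pulldowns. This matters
   in designs where the two classes have overlapping backgrounds.
2. **Contaminant removal.** Identifiers on a cRAP-style contaminant list are
   removed, matching case-insensitively on accession and gene symbol
   (`contaminant_match_on = "both"`) because public contaminant lists mix
   identifier styles.
3. **Nuclear restriction.** A protein is kept when any keyword of
   `nuclear_keywords` (default: nucleus, nucleolus, chromosome, nucleoplasm)
   occurs as a case-insensitive substring of its subcellular-location or
   function annotation, emulating a UniProt Function / Subcellular location
   screen. The matching rule is a package decision — annotation text is free
   prose and admits no exact rule; substring matching over a short
   keyword list is transparent and auditable. Proteins without an annotation
   record are dropped with a warning by default.
4. **Locus specificity.** A protein is flagged locus-specific when it is
   detected (PSM ≥ 1) in at least `locus_min_gd4z4_samples` (default 2)
   gD4Z4 pulldowns while detected in at most `control_max_replicates`
   (default 1) gMYOD1 pulldowns — recurrent at the target locus, absent or
   sporadic in the control pulldowns.

Steps 2 and 3 are pure set intersections, so their order is immaterial; the
test suite asserts this on random inputs. Raising `min_psm` or
`min_replicates` can only shrink the retained set (monotonicity), also
asserted.

Reporting averages distinct-peptide counts and coverage per target class
over *all* like-class samples, zeros included — this is how non-integer
averages like 4.7 or 1.6 arise from three pulldowns. The replicate filter is
defined on PSM counts while the report shows peptide counts; both matrices
are therefore maintained, the PSM matrix driving filtering and the peptide
matrix driving the report. Report tables round half-away-from-zero to one
decimal; full precision is kept internally.

```{r hits}
sim <- simulate_enchip(enchip_sim_config(seed = 20))
res <- run_hit_pipeline(sim$evidence, sim$design, sim$annotations,
                        sim$contaminants)
res
head(format_hit_table(res), 3)
```

## Overrepresentation testing

For a query of $n$ genes drawn from a universe of $N$ genes, a term with $K$
annotated genes and an observed overlap $k$, the one-sided enrichment
p-value is the hypergeometric upper tail

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

accumulated in log space (`lchoose`) so large universes do not overflow.
Only overrepresentation is tested; depletion is not. Gene symbols are
case-folded and de-duplicated before counting, and query genes absent from
the universe are dropped by default. The Bonferroni correction multiplies by
the number of terms actually tested — all terms in the collection, not only
those with non-zero overlap, the strictest reading. No term-graph
propagation or ancestry handling is attempted; the collection is taken as
given.

## Delta-delta-Ct quantification

With target Ct $C_T$ and reference Ct $C_R$ per biological replicate, the
method computes $\Delta Ct = C_T - C_R$, subtracts the mean control-condition
$\Delta Ct$ to give $\Delta\Delta Ct$, and reports the fold change
$2^{-\Delta\Delta Ct}$. Three decisions the textbook description of the method leaves
open:

- multiple reference genes are combined by the arithmetic mean of their Cts
  (on the Ct scale this is the log of their geometric-mean expression, the
  usual multi-reference convention);
- the baseline is the arithmetic mean of control-replicate $\Delta Ct$,
  which makes the geometric mean of control folds exactly 1 (asserted to
  1e-9 in tests);
- summary mean and SD are computed on the linear fold scale, matching the
  convention of plotting the mean fold over biological replicates with its
  standard deviation as the error bar.

The method presumes equivalent amplification efficiencies of target and
references. `efficiency_check()` fits mean Ct against $\log_{10}$ template
amount over a dilution series ($E = 10^{-1/\text{slope}} - 1$) and declares
equivalence when the slope of $\Delta Ct$ versus $\log_{10}$ amount is below
0.1 cycles per ten-fold dilution in absolute value — the standard validation
threshold for the uncorrected delta-delta-Ct formula. Undetected wells are
flagged and excluded, never silently imputed to a ceiling Ct.

## Exact Mann-Whitney U

At three replicates per group a normal-approximation rank test is
meaningless, so the exact test enumerates all $\binom{n_1+n_2}{n_1}$
relabelings of the observed pooled values. Ties need no correction — they
are handled naturally by enumerating the observed values themselves (U uses
average ranks, contributing 0.5 per tied pair). The one-sided tail is the
fraction of relabelings with $U \le \min(U_1, U_2)_{obs}$ and the two-tailed
p doubles it, capped at 1. `method = "auto"` switches to a tie-corrected,
continuity-corrected normal approximation above $n_1 + n_2 = 12$.

A structural consequence worth stating: with $n_1 = n_2 = 3$ the smallest
achievable two-tailed exact p is $2/\binom{6}{3} = 0.1$. Reported
significance at $p \le 0.05$ under this design therefore cannot come from
the exact test; both the exact and approximate methods are provided and
every result records which was used, so downstream reports never have to
guess.

```{r mw}
mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
```

## ChIP-qPCR percent input

Enrichment is expressed as percent input: the input Ct is adjusted for the
input fraction $f$ by subtracting $\log_2(1/f)$ cycles, then
$\%input = 100 \times 2^{(Ct_{input,adj} - Ct_{IP})}$. The IgG control is
compared statistically (exact Mann-Whitney per site) rather than subtracted,
so negative enrichments cannot arise and the control's own variability is
respected. Percent input is invariant to shifting IP and input Cts jointly,
which the tests assert.

## The synthetic-data generators

The generators exist so every stage has planted, recoverable truth without
any external download.

**enChIP-MS** (`simulate_enchip`): the default design is three gD4Z4
pulldowns (one per guide) and two gMYOD1 pulldowns, all singleton FLAG IPs —
the guide structure this pipeline targets; per-class sample counts are a
free choice, so three-vs-two was fixed once as the smallest design in which
both the "more than one target sample" and "at most a single control
replicate" clauses bind. PSM counts are Poisson: locus proteins at
`lambda_signal = 6` in gD4Z4 samples (a typical spectral count for a
mid-abundance specific interactor) and `lambda_background = 0.3` elsewhere —
a sporadic nonspecific-carryover rate chosen so that locus proteins are
usually absent from controls, the detection pattern the locus-specificity
rule is built around; shared background proteins draw the background rate everywhere;
contaminants and non-nuclear decoys draw signal-level counts in every
sample. Each observation is independently zeroed with `dropout_prob = 0.1`.
Distinct-peptide counts are uniform on 1..PSM and coverage is proportional
to distinct peptides. Contaminants are annotated as nuclear *on purpose*, so
that the contaminant list — not the nuclear filter — is what removes them
and the two filters remain separately testable. An optional
negative-binomial `dispersion` adds overdispersion; the default stays pure
Poisson, the simplest model consistent with presence/absence filtering
semantics.

What this generator does **not** emulate: correlated abundances across
samples, protein-loading differences between pulldowns, shared-peptide
protein inference ambiguity, or realistic contaminant abundance profiles.
Passing the planted-recovery tests shows the filtering logic is correct
under the stated sampling model; it does not validate performance on real
search-engine output.

**RT-qPCR** (`simulate_qpcr`): per-well
$Ct = \text{baseline} - \log_2(\text{relative expression}) + N(0, \sigma)$,
technical triplicates over three biological replicates, reference genes
(RPL27, RPL13A, GAPDH baselines 18/19/20 cycles) unaffected by condition.
$\sigma = 0.2$ cycles is a typical well-to-well SD for SYBR assays; the
noisy-recovery tests use $\sigma = 0.3$ deliberately above it. Plate
effects, efficiency differences and detection limits are not modeled.

**Gene sets** (`simulate_geneset_universe`): one term planted to share a
fixed overlap with the query, all others uniform random.

All generators run off a single integer seed; identical seeds give
byte-identical output files (asserted), different seeds differ.

## Numerical choices

- Hypergeometric tail sums in log space with max-subtraction; agreement with
  `stats::phyper` to 1e-12 and with exhaustive subset enumeration for every
  tuple with $N \le 12$ is asserted.
- Exact Mann-Whitney compares permuted U values with a 1e-9 epsilon so that
  half-integer U values from ties never fall to floating-point comparison.
- Report rounding is half-away-from-zero with a machine-epsilon guard
  (`round_half_up(2.35, 1)` is 2.4 even though 2.35 has no exact binary
  representation).
- Duplicate evidence rows for one (protein, sample) are summed for counts
  and maximum-taken for coverage; absent pairs are exact zeros, so matrix
  column sums conserve the evidence totals.
- Output tables sort by gene symbol then accession; enrichment results by
  raw p then term id — deterministic files for a fixed input.

## Problem sizes in the shipped analyses

The bundled drivers and checks use a 48-protein enChIP simulation (8 locus,
30 background, 5 contaminants, 5 decoys) over 5 samples, a 200-gene
universe with 20 terms, 3 biological × 3 technical qPCR replicates, 500
random small-sample Mann-Whitney comparisons against the enumeration oracle,
the full hypergeometric grid to $N = 12$, and 200 Monte-Carlo qPCR
simulations at $\sigma = 0.3$. These sizes were chosen to exercise every
code path at the replicate scale of the emulated experiments.

## Known limitations

- Spectral counting is presence/absence-oriented; no intensity-based or
  efficiency-corrected (Pfaffl) quantification is provided.
- The nuclear keyword screen inherits the coarseness of free-text
  annotations: a cytoplasmic protein whose function text mentions
  "chromosome" will be kept.
- The exact Mann-Whitney p is bounded below by $2/\binom{n_1+n_2}{n_1}$;
  with three-vs-three replicates no result can reach 0.05.
- Contaminant-list and annotation snapshots are user inputs, never bundled
  as truth; results are only as current as the snapshots supplied.
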
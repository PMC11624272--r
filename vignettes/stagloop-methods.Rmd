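---
title: "Models and methods behind stagloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stagloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagloop)
library(dplyr)
```

## The biological problem

Ewing sarcoma is driven by the fusion transcription factor EWS::FLI1, which
binds GGAA motifs; chained GGAA motifs (microsatellites) act as
neoenhancers, with runs of more than four motifs ("long" repeats) bound most
strongly. The cohesin complex comes in two flavors distinguished by the
STAG1 or STAG2 subunit, and STAG2 loss — a recurrent event associated with
poor prognosis — rewires the enhancer–promoter contacts that connect these
neoenhancers to their target genes. stagloop implements the quantitative
backbone of this analysis: repeat scanning, calibrated ChIP signal,
promoter capture Hi-C (PCHi-C) loop classification and strength, local
contact pileups, gene-level integration, and a STAG2-loss expression
signature tied to patient survival. Every stage can be exercised on
synthetic data with planted ground truth.

## GGAA repeat scanning

`scan_ggaa_runs()` chains GGAA occurrences left to right: two consecutive
motifs belong to one run when the gap between them (end of one to start of
the next) is at most `max_gap = 5` nt. Because the motif is fixed-length
and cannot overlap itself, greedy chaining over the sorted occurrence list
provably yields maximal runs. Peaks are classified by the best run
overlapping them by at least 1 bp: `long` (n > 4), `short` (1–4), `none`.

Two conventions were genuinely open and are exposed as flags. The scanner
defaults to both strands (GGAA and TTCC), because the microsatellite is
double-stranded; `strand_mode = "forward"` reproduces single-strand
behavior. The gap is measured edge to edge, the most natural reading of a
"distance between motifs"; a start-to-start convention would shift every
threshold by 4 nt.

## Spike-in calibration

With a fixed fraction of spike-in chromatin (5% mouse in a human
experiment), the occupancy ratio

$$ OR = \frac{W_m \cdot IP_h}{W_h \cdot IP_m} $$

relates input (W) and immunoprecipitated (IP) read counts in the target
(h) and spike-in (m) genomes. `calibrate_coverage()` first scales a
coverage track to mean 1 over its bins — removing sequencing depth, which
is the interpretation we adopt for "normalized by coverage"; a
counts-per-million convention would differ only by a constant and cancel in
every comparison — and then multiplies by OR. Per-peak comparisons use
`log2((mean_A + c)/(mean_B + c))` with pseudocount `c = 0.1` on the
calibrated scale (configurable; it only matters for near-empty peaks).

## Contact matrices and normalization

`contact_matrix` stores sparse binned counts (3 kb bins by default) over a
bin table whose bait flags mark capture-targeted promoter bins.
`downsample_to_match()` equalizes the on-target totals (summed counts of
pixels touching at least one bait) across conditions by a multivariate
hypergeometric draw — subsampling without replacement at single-count
granularity, so totals are hit exactly and support can only shrink.
Off-target pixels are thinned at the same global rate. Replicate conditions
are merged by pixel-wise count addition before normalization.

Normalization is the two-step scheme used for bait-row matrices:

1. **Row normalization** divides each row of the symmetric matrix by its
   row sum; rows with positive sums then sum to exactly 1. Row division
   breaks symmetry, so the result is stored row-oriented.
2. **Decay normalization** computes, per chromosome, the expected value at
   each bin distance as the mean row-normalized value over *bait rows
   only*, counting zeros at every position a bait row can reach within its
   chromosome. Each pixel is divided by the expected value at its distance,
   giving an observed/expected (O/E) matrix in which pure distance decay is
   flat at 1. The output is restricted to bait rows: PCHi-C matrices carry
   no information in other rows, and their inclusion would make the O/E
   scale position-dependent. Inter-chromosomal pixels have no distance and
   are dropped with a warning.

Loop strength is the O/E value at the loop's single pixel (0 when absent);
a window flag averages a small square instead, for users who prefer
smoothing. Differential strength is `log2((s_KO + eps)/(s_WT + eps))` with
`eps` set to 10% of the median positive strength — a data-scaled
pseudocount that keeps lost loops finite without drowning real changes.

## Loop classification

Calls are filtered at `n_reads >= 5` and `score > 3` (inclusive on reads,
strict on score — the bounds behave exactly this way in the tests). Loop
identity across cell lines is exact bin-pair equality on the shared 3-kb
grid; fuzzy anchor matching would introduce unstated parameters. The two
consensus sets are loops called in both STAG2-proficient lines (P and WT)
and loops called in both KO clones. Within their union, a loop is `common`
when called in at least 3 of the 4 lines, `lost` when called only in the
two proficient lines, `gained` when called only in the two KO clones;
every other pattern (necessarily a two-line pattern straddling conditions)
is `unclassified` and excluded downstream, as it belongs to neither
consensus set. Loop length is measured midpoint to midpoint of the anchor
bins and summarized over the strata relevant to cohesin biology
(< 80 kb, 80–800 kb, 800 kb–1 Mb, > 1 Mb).

## Local pileups

`local_pileup()` aggregates O/E signal in windows centered on the diagonal
at each anchor (default half-width 500 kb): element (i, j) is the mean over
anchors of the O/E value at (anchor + i, anchor + j). Three numerical
choices matter. Missing pixels are imputed at 1 — the expected value —
because capture matrices are zero-dominated and zero imputation would bias
every mean downward. Windows crossing a chromosome end are dropped rather
than padded, avoiding partial-window bias; the anchor count actually used
is reported. The log2 transform, when requested, is applied last, to the
mean. `stratified_pileups()` repeats this per (repeat class × cohesin)
stratum and reports per-stratum anchor counts; an empty stratum is
reported, not fatal.

## Gene-level integration

Promoters default to TSS ± 2 kb (a conventional window; the capture
design's own fragment map can be supplied via explicit promoter columns),
and a gene's bait bins are all bins overlapping its promoter, pooled
across baits. Enhancer classes follow a strict precedence: `P` when a
GGAA-bearing peak overlaps the promoter itself; otherwise `distal_long` /
`distal_short` when a classified loop links a bait bin to a bin holding a
long / short repeat peak; otherwise `none`. Per-gene contact change is
`lost`/`gained` only when *all* of a gene's loops are; otherwise the mean
differential strength decides `up`/`down` outside a dead-band of
|Δlog2| = 0.25, and `common` inside it. The dead-band is a reporting
threshold for boxplot categories, not a significance claim. Group
comparisons of expression changes use the rank tests standard for such
figures (Mann–Whitney for two groups, Kruskal–Wallis for more).

## Signature classifier and survival

A directed signature is the intersection of two DEG contrasts at
FDR < 0.05 (strict) with concordant fold-change sign. The two phenotype
models are built on the cohort's own expression scale — no per-gene
z-scoring, because the construction is defined on raw dataset values: the
KO model takes each upregulated gene at its cohort maximum and each
downregulated gene at its minimum; the WT model is the opposite.
`classify_cohort()` runs two-group k-means (Euclidean) initialized at
these centroids. We iterate Lloyd updates to convergence rather than
stopping after one assignment, since "k-means with initialized centroids"
conventionally means the full algorithm; distance ties break toward the WT
cluster, the conservative side for a poor-prognosis call. Samples in the
cluster whose converged centroid lies nearer the KO model are
`signature-like`. The procedure is deterministic given the initialization,
invariant to gene order and to extra genes in the table, and flipping the
sign of all expression values swaps the two labels exactly.

Survival comparison uses the stock Kaplan–Meier and two-group Cox
proportional-hazards machinery (the `survival` package), with
`signature-different` as the reference. `flag_wtstar()` is one defensible
algorithmic reading of "wild-type samples clustering with mutants": k-means
(k = 2) on the top two principal components of the full transcriptome,
flagging WT samples in the majority-mutant cluster; the published analysis
did not state an algorithm, so this choice is labeled as ours.

## The synthetic-data generator

The generator defines the study conditions under which all tests run.

* **Genome**: i.i.d. background at GC 0.41 with *every* GGAA/TTCC
  occurrence scrubbed from the background (a stricter variant of rejecting
  motifs near planted runs), so the planted motif count is exact and
  truth recovery is unambiguous. Runs are spliced in at deterministic
  positions; gap fillers are T homopolymers, which cannot create either
  motif at a junction.
* **ChIP counts**: independent Poisson draws with `wh ~ Pois(depth)`,
  `wm, ipm ~ Pois(0.05 depth)`, `iph ~ Pois(or_true · depth)`, so the OR
  estimator recovers `or_true` in expectation (ratio bias is O(1/depth)).
* **Contact maps**: capture-style — pixels exist only in bait rows, within
  a maximum interaction range, with expected count `base · d^(−α)`
  (default α = 1, the canonical contact-decay exponent) and planted loop
  pixels multiplied by their fold. Default fixtures place baits at least
  the full range away from chromosome ends, which makes every bait row's
  distance profile identical and the noiseless O/E exactly 1; Poisson
  noise is optional. This emulates the statistical structure of capture
  data, not its fragment-level detail.
* **Loop calls**: per-line emission with a detection probability; read
  counts are `5 + NegBin(mu = 15, size = 2)` and scores
  `3.01 + Gamma(2, 0.5)` — heavy-tailed like real call tables; these
  defaults are recorded, not inferred from any dataset. Optional
  sub-threshold decoys include the exact boundary records
  (`n_reads = 4`, `score = 3`).
* **Cohort**: signature genes shift by ±effect (default 2 log2 units) in
  signature-like patients plus Gaussian noise; survival is exponential at
  0.01/day baseline with the hazard multiplied by the planted ratio
  (default 3) for signature-like patients. Censoring is uniform over a
  follow-up horizon solved from the requested censored fraction (default
  0.2) under the baseline hazard, keeping censoring independent of the
  event process.

What passing tests do and do not show: the generator reproduces the
*statistical structure* the methods assume — power-law decay, planted
enrichment folds, proportional hazards, separable expression shifts. It
does not emulate mappability, fragment-length, or chromatin-state
artifacts of real libraries, genuine ChiCAGO background models, or
cross-platform cohort batch effects; exact truth recovery here therefore
validates the computations, not the upstream experimental pipeline.

## Problem sizes and determinism

Default test and acceptance problem sizes are chosen to make the planted
signal estimable without waste: 1,000 random 500-bp sequences for the
scanner cross-check, ≤ 200-bin matrices for dense-oracle comparisons, a
2,500-bait-row chromosome with 50 planted anchors for pileup recovery
(enough bait rows that 50 planted pixels perturb the expected-by-distance
curve by under 5%), 200-patient cohorts, and 50–100 seeded survival
replicates. Every stochastic generator takes an explicit integer seed and
restores the caller's RNG state; identical seeds give byte-identical
outputs.

## A worked miniature study

```{r study, eval = FALSE}
st <- simulate_study(seed = 1)
loops <- classify_loops(filter_loop_calls(st$calls), st$bins)
ann <- annotate_peaks(st$peaks, st$genome)
assign_enhancer_class(st$genes, ann, loops, st$bins) |>
  count(enhancer_class)

sig <- intersect_degs(st$deg_patients, st$deg_cells)
model <- build_signature_model(st$cohort$expression, sig)
labels <- tidy(classify_cohort(st$cohort$expression, model))
glance(survival_compare(labels, st$cohort$survival))
```

## Known limitations

* Loop identity is exact bin-pair matching; anchors drifting across a bin
  boundary between libraries would fragment a loop's presence pattern.
* Decay normalization assumes intra-chromosomal contacts; trans pixels are
  dropped.
* `flag_wtstar()` and the promoter window are defensible conventions for
  under-specified steps, not reconstructions of unpublished parameters.
* The generator's score and read-count distributions are stated defaults;
  conclusions about filter behavior on real call tables depend only on the
  thresholds, not on these shapes.
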
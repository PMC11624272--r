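# stagloop

Analysis of STAG2-dependent enhancer–promoter contacts in Ewing sarcoma.

Ewing sarcoma is driven by the EWS::FLI1 fusion transcription factor, which
binds GGAA motifs; chained runs of more than four motifs ("long" GGAA
microsatellites) act as neoenhancers. Loss of the cohesin subunit STAG2 —
a recurrent, prognosis-relevant event — rewires the chromatin loops that
connect these enhancers to target promoters. `stagloop` implements the
computational core of this analysis for R, end to end:

* **GGAA microsatellite scanning** — maximal chaining of GGAA/TTCC motifs
  with a gap tolerance (default 5 nt); peak annotation into
  `long` (n > 4) / `short` / `none` repeat classes; blacklist + q-value
  peak filtering.
* **Spike-in ChIP calibration** — the occupancy ratio
  `OR = (Wm · IPh) / (Wh · IPm)` from input/IP read counts in target and
  spike-in genomes, coverage calibration, and per-peak log2 fold changes.
* **Promoter capture Hi-C loops** — call filtering (≥ 5 reads, score > 3),
  condition consensus sets, `common` (≥ 3 of 4 lines) / `gained` (KO
  only) / `lost` (STAG2-proficient only) classification, and loop-length
  strata (80–800 kb cohesin range, > 1 Mb inter-TAD contacts).
* **Contact-matrix normalization** — sparse 3-kb binned matrices,
  downsampling to exactly matched on-target (bait-touching) totals,
  bait-row normalization, distance-decay (observed/expected)
  normalization, and per-loop O/E strengths.
* **Anchor-centered pileups** — local O/E aggregation around binding
  sites (default ± 500 kb), stratified by repeat class and cohesin status.
* **Gene integration** — enhancer-contact classes
  (`P` / `distal_long` / `distal_short` / `none`, with that precedence),
  per-gene contact-change labels, cohesin/CTCF-anchored gene selection,
  and rank-test group comparisons of expression changes.
* **Patient stratification** — a directed signature from two DEG
  contrasts (FDR < 0.05, concordant sign), extreme-phenotype centroid
  models (per-gene cohort max/min by direction), centroid-initialized
  two-group k-means into `signature-like` / `signature-different`, PCA
  projection, and Kaplan–Meier / Cox proportional-hazards survival
  comparison.
* **Synthetic data** — generators for every input (genome with planted
  runs, peaks, calibration counts, contact maps with planted loops, loop
  calls, DEG tables, survival cohorts) with recorded ground truth, so the
  whole pipeline is testable offline.

Functions are data-frame-first and return tibbles; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` heatmaps, PCA and
Kaplan–Meier plots.

## Worked example

```r
library(stagloop)
library(dplyr)

st <- simulate_study(seed = 1)              # miniature study, planted truth

loops <- classify_loops(filter_loop_calls(st$calls), st$bins)
loops |> count(label)
#> # A tibble: 3 × 2
#>   label      n
#>   <chr>  <int>
#> 1 common     1
#> 2 gained     1
#> 3 lost       1

ann <- annotate_peaks(st$peaks, st$genome)
assign_enhancer_class(st$genes, ann, loops, st$bins) |>
  select(gene_id, enhancer_class)
#> # A tibble: 5 × 2
#>   gene_id        enhancer_class
#>   <chr>          <chr>
#> 1 g_P            P
#> 2 g_long_lost    distal_long
#> 3 g_short_common distal_short
#> 4 g_long_gained  distal_long
#> 5 g_none         none

sig <- intersect_degs(st$deg_patients, st$deg_cells)
model <- build_signature_model(st$cohort$expression, sig)
labels <- tidy(classify_cohort(st$cohort$expression, model))
survival_compare(labels, st$cohort$survival)
#> <survival_comparison> HR = 3.286 [2.157, 5.005], p = 3.02e-08
#>   (120 samples, 108 events; reference: signature-different)
```

The loop labels mirror the planted presence patterns (one loop called in
all four cell lines, one only in the KO clones, one only in the
STAG2-proficient lines); gene classes follow peak–promoter overlap and
loop linkage; and the hazard-ratio estimate recovers the planted value of
3 for signature-like patients.

A thin command-line wrapper over the same functions lives at
`inst/cli/stagloop.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/stagloop.R", package = "stagloop"))')
Rscript $CLI simulate --out-dir study --seed 1
Rscript $CLI scan-repeats --fasta study/genome.fa --peaks study/peaks.bed \
        --out study/peaks_annotated.tsv
Rscript $CLI classify-loops --calls study/loop_calls.tsv \
        --bins study/bins.tsv --out study/loops.tsv
```

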
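#' Simulate a coherent miniature study with full planted truth
#'
#' Builds every input of the pipeline on one synthetic chromosome so the
#' whole analysis -- repeat scanning, loop classification, contact
#' normalization, gene-class assignment, signature classification and
#' survival -- can be run end to end and checked against planted truth.
#'
#' The layout plants five genes with one bait (TSS) bin each: a gene with a
#' long GGAA run at its promoter (class `P`), a gene looped to a distal
#' long repeat whose loop is present only in the STAG2-proficient lines
#' (class `distal_long`, contact change `lost`), a gene looped to a distal
#' short repeat in all lines (`distal_short`, `common`), a gene looped to a
#' distal long repeat only in the KO clones (`distal_long`, `gained`), and
#' a gene with no GGAA contact at all (`none`). Loop calls are emitted for
#' the four cell lines (P, WT, KO1, KO2), contact maps for the two merged
#' conditions, and a patient cohort carries a signature derived from two
#' concordant DEG contrasts, tied to survival with the planted hazard
#' ratio.
#'
#' @param seed Integer seed driving every draw.
#' @param contact_noise `"none"` for exact contact expectations (the
#'   noiseless truth-recovery setting) or `"poisson"`.
#' @param cohort_noise_sd Gaussian expression noise in the cohort (0 makes
#'   the classifier exact).
#' @param n_patients Cohort size.
#' @param hr Planted hazard ratio for signature-like patients.
#' @return List with `genome`, `runs`, `peaks`, `bins`, `loops` (planted),
#'   `calls` (long per-line table), `maps` (list of raw WT/KO matrices),
#'   `genes`, `deg_efkd`, `deg_patients`, `deg_cells`, `cohort`, and
#'   `truth` (tibbles of planted gene classes, contact changes, loop
#'   labels and patient groups).
#' @export
simulate_study <- function(seed = 1L, contact_noise = c("none", "poisson"),
                           cohort_noise_sd = 0, n_patients = 120L, hr = 3) {
  contact_noise <- match.arg(contact_noise)
  chrom_len <- 900000L
  bs <- 3000L
  tss_bin <- c(g_P = 110L, g_long_lost = 120L, g_short_common = 130L,
               g_long_gained = 140L, g_none = 150L)
  oe_bin <- c(g_long_lost = 160L, g_short_common = 165L, g_long_gained = 180L)
  bin_center <- function(b) (b - 1L) * bs + bs %/% 2L

  # planted GGAA runs: one inside the P gene's promoter, one per distal bin
  run_spec <- tibble(
    chrom = "simchr1",
    start = c(bin_center(tss_bin[["g_P"]]) + 100L,
              (oe_bin - 1L) * bs + 1400L),
    n_motifs = c(6L, 7L, 2L, 8L),
    gap = 0L,
    strand = "+"
  )
  sim <- simulate_genome(n_chrom = 1L, chrom_len = chrom_len,
                         run_spec = run_spec, seed = seed)
  peaks <- simulate_peaks(sim, n_background = 8L, seed = seed)

  bins <- simulate_bins(c(simchr1 = chrom_len), bin_size = bs,
                        bait_bins = unname(tss_bin))

  loops <- tibble(
    gene_id = c("g_long_lost", "g_short_common", "g_long_gained"),
    bait_bin = unname(tss_bin[c("g_long_lost", "g_short_common",
                                "g_long_gained")]),
    oe_bin = unname(oe_bin),
    fold = 4,
    in_WT = c(TRUE, TRUE, FALSE),
    in_KO = c(FALSE, TRUE, TRUE)
  )
  maps <- simulate_contact_maps(
    bins, loops, conditions = c("WT", "KO"), decay_exp = 1, base = 100,
    max_range = 300000L, noise = contact_noise, seed = seed
  )
  lc <- simulate_loop_calls(loops, bins, detect_prob = 1, seed = seed)

  genes <- tibble(
    gene_id = names(tss_bin),
    chrom = "simchr1",
    tss = bin_center(unname(tss_bin)),
    strand = "+"
  )
  deg_efkd <- tibble(
    gene_id = names(tss_bin),
    log2fc = c(-1.2, -1.0, 0.8, -0.9, 0.1),
    fdr = c(1e-4, 1e-4, 1e-3, 1e-3, 0.6)
  )

  dp <- simulate_deg_pair(n_concordant = 40L, n_discordant = 15L,
                          n_nonsig = 20L, seed = seed)
  cohort <- simulate_cohort(
    n_patients = n_patients, n_genes = 300L, signature = dp$truth,
    effect = 2, noise_sd = cohort_noise_sd, hr = hr, censor_rate = 0.2,
    seed = seed
  )

  truth <- list(
    gene_class = tibble(
      gene_id = names(tss_bin),
      enhancer_class = c("P", "distal_long", "distal_short", "distal_long",
                         "none")
    ),
    contact_change = tibble(
      gene_id = c("g_long_lost", "g_short_common", "g_long_gained"),
      contact_change = c("lost", "common", "gained")
    ),
    loop_label = loops |>
      transmute(.data$bait_bin, .data$oe_bin,
                label = case_when(
                  .data$in_WT & .data$in_KO ~ "common",
                  .data$in_WT ~ "lost",
                  TRUE ~ "gained"
                )),
    patient_group = cohort$labels,
    signature = dp$truth
  )

  list(genome = sim$genome, runs = sim$runs, peaks = peaks, bins = bins,
       loops = loops, calls = lc$calls, call_truth = lc$truth, maps = maps,
       genes = genes, deg_efkd = deg_efkd, deg_patients = dp$deg_a,
       deg_cells = dp$deg_b, cohort = cohort, truth = truth)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Materializes every [simulate_study()] table in the formats the pipeline
#' (and its command-line interface) consumes: FASTA genome, BED peaks,
#' TSV bin/pixel/call/annotation/expression/survival tables and a
#' `truth.json` with the planted ground truth.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genome_fasta(study$genome, p("genome.fa"))
  write_peaks_bed(study$peaks |>
                    select("chrom", "start", "end", "name", "q"),
                  p("peaks.bed"))
  write_table_tsv(study$bins, p("bins.tsv"))
  for (cond in names(study$maps)) {
    write_table_tsv(study$maps[[cond]]$pixels,
                    p(sprintf("pixels_%s.tsv", cond)))
  }
  write_table_tsv(study$calls, p("loop_calls.tsv"))
  write_table_tsv(study$genes, p("genes.tsv"))
  write_table_tsv(study$deg_efkd, p("deg_efkd.tsv"))
  write_table_tsv(study$deg_patients, p("deg_patients.tsv"))
  write_table_tsv(study$deg_cells, p("deg_cells.tsv"))
  write_table_tsv(study$cohort$expression, p("expression.tsv"))
  write_table_tsv(study$cohort$survival, p("survival.tsv"))
  truth <- study$truth
  truth$runs <- study$runs
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
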
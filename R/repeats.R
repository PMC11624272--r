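#' Scan a DNA sequence for chained GGAA microsatellite runs
#'
#' EWS::FLI1 binds GGAA motifs, and chained motifs (microsatellites) act as
#' neoenhancers in Ewing sarcoma. Two consecutive motif occurrences belong to
#' the same run when the gap between them -- measured from the end of one
#' motif to the start of the next -- is at most `max_gap` nucleotides. Runs
#' are maximal: chaining is greedy left-to-right over the sorted occurrence
#' list, which is provably maximal for a fixed-length motif. A run of a
#' single motif is reported with `n_motifs = 1`.
#'
#' With `strand_mode = "both"` (default) the reverse-strand motif (TTCC on
#' the forward sequence) is scanned as well and reported separately with
#' strand `"-"`; coordinates always refer to the forward strand.
#'
#' @param sequence A single DNA sequence: character string or
#'   [Biostrings::DNAString]. Letters other than A, C, G, T, N are an error;
#'   N never matches.
#' @param max_gap Maximum gap (nt) between consecutive motifs in one run.
#' @param strand_mode `"both"` or `"forward"`.
#' @param chrom Optional sequence name attached to the output.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `n_motifs`, `strand`, ordered by `start`. A run with `n_motifs = n` and
#'   zero internal gaps spans `4 * n` bp.
#' @examples
#' scan_ggaa_runs("GGAAGGAAGGAAGGAAGGAA")   # one run, n = 5
#' scan_ggaa_runs("GGAATTTTTGGAA")          # gap 5 -> one run, n = 2
#' scan_ggaa_runs("GGAATTTTTTGGAA")         # gap 6 -> two runs of n = 1
#' @export
scan_ggaa_runs <- function(sequence, max_gap = 5,
                           strand_mode = c("both", "forward"),
                           chrom = NA_character_) {
  strand_mode <- match.arg(strand_mode)
  if (max_gap < 0) abort("max_gap must be >= 0")
  seq_chr <- toupper(as.character(sequence))
  if (length(seq_chr) != 1) abort("scan_ggaa_runs() takes a single sequence")
  if (nchar(seq_chr) > 0 && str_detect(seq_chr, "[^ACGTN]")) {
    abort("sequence contains letters other than A, C, G, T, N")
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_motifs = integer(), strand = character())
  if (nchar(seq_chr) < 4) return(empty)

  dna <- Biostrings::DNAString(seq_chr)
  runs_for <- chain_motif_starts(
    Biostrings::start(Biostrings::matchPattern("GGAA", dna)), max_gap
  )
  runs_for$strand <- rep("+", nrow(runs_for))
  out <- runs_for
  if (strand_mode == "both") {
    runs_rev <- chain_motif_starts(
      Biostrings::start(Biostrings::matchPattern("TTCC", dna)), max_gap
    )
    runs_rev$strand <- rep("-", nrow(runs_rev))
    out <- bind_rows(runs_for, runs_rev)
  }
  out |>
    mutate(chrom = chrom) |>
    select("chrom", "start", "end", "n_motifs", "strand") |>
    arrange(.data$start, .data$strand)
}

# Chain 1-based motif start positions (motif length 4) into runs; gap between
# consecutive motifs is start[i+1] - (start[i] + 4). Returns 0-based half-open
# run coordinates.
chain_motif_starts <- function(starts, max_gap) {
  if (length(starts) == 0) {
    return(tibble(start = integer(), end = integer(), n_motifs = integer()))
  }
  starts <- sort(as.integer(starts))
  run_id <- cumsum(c(1L, as.integer(diff(starts) - 4L > max_gap)))
  tibble(motif_start = starts, run_id = run_id) |>
    group_by(.data$run_id) |>
    summarise(
      start = min(.data$motif_start) - 1L,
      end = max(.data$motif_start) + 3L,
      n_motifs = n(),
      .groups = "drop"
    ) |>
    select("start", "end", "n_motifs")
}

#' Scan every sequence of a genome for GGAA runs
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @inheritParams scan_ggaa_runs
#' @return Tibble of runs across all sequences (see [scan_ggaa_runs()]).
#' @export
scan_genome_runs <- function(genome, max_gap = 5,
                             strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  seqs <- if (is.character(genome)) genome else as.character(genome)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    abort("genome sequences must be named")
  }
  imap(seqs, function(s, nm) {
    scan_ggaa_runs(s, max_gap = max_gap, strand_mode = strand_mode, chrom = nm)
  }) |> list_rbind()
}

#' Annotate peaks with their best GGAA run and repeat class
#'
#' For each peak, `best_n` is the maximum number of chained motifs over all
#' runs overlapping the peak by at least 1 bp (both strands unless
#' `strand_mode = "forward"`). Classes follow the convention used for
#' EWS::FLI1 sites: `long` for runs of more than four motifs, `short` for one
#' to four, `none` when no run touches the peak.
#'
#' @param peaks Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @inheritParams scan_ggaa_runs
#' @return `peaks` with `best_n` and `repeat_class` columns appended.
#' @export
annotate_peaks <- function(peaks, genome, max_gap = 5,
                           strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  peaks <- as_tibble(peaks)
  seqs <- if (is.character(genome)) genome else as.character(genome)
  lens <- setNames(nchar(seqs), names(seqs))
  unknown <- !peaks$chrom %in% names(lens)
  if (any(unknown)) {
    abort(sprintf("peak(s) on unknown chromosome: %s",
                  paste(utils::capture.output(print(
                    as.data.frame(head(peaks[unknown, c("chrom", "start", "end")], 5))
                  )), collapse = "\n")))
  }
  if (any(peaks$start < 0 | peaks$end > lens[peaks$chrom])) {
    abort("peak outside genome bounds")
  }
  runs <- scan_genome_runs(genome, max_gap = max_gap, strand_mode = strand_mode)
  best_n <- integer(nrow(peaks))
  if (nrow(runs) > 0 && nrow(peaks) > 0) {
    ov <- overlap_pairs(peaks, runs)
    if (nrow(ov) > 0) {
      agg <- ov |>
        mutate(n_motifs = runs$n_motifs[.data$subject_idx]) |>
        group_by(.data$query_idx) |>
        summarise(best_n = max(.data$n_motifs), .groups = "drop")
      best_n[agg$query_idx] <- agg$best_n
    }
  }
  peaks |>
    mutate(
      best_n = best_n,
      repeat_class = case_when(
        best_n > 4 ~ "long",
        best_n >= 1 ~ "short",
        TRUE ~ "none"
      )
    )
}

#' Filter peaks by q value and a blacklist
#'
#' Retains unique peaks (identical `chrom`/`start`/`end` collapsed to one
#' record) with `q >= q_min` and no overlap with any blacklist interval. The
#' `q` column is on the -log10 scale emitted by the peak caller, so the
#' default `q_min = 5` keeps peaks with q-value at most 1e-5.
#'
#' @param peaks Data frame with `chrom`, `start`, `end` and a `q` column.
#' @param blacklist Optional data frame of intervals to exclude.
#' @param q_min Minimum (inclusive) -log10 q value.
#' @return Filtered peak tibble.
#' @export
filter_peaks <- function(peaks, blacklist = NULL, q_min = 5) {
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  if (!"q" %in% names(peaks)) abort("peaks must carry a `q` column (-log10 scale)")
  out <- as_tibble(peaks) |>
    distinct(.data$chrom, .data$start, .data$end, .keep_all = TRUE) |>
    filter(.data$q >= q_min)
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(out) > 0) {
    n_hits <- GenomicRanges::countOverlaps(
      intervals_to_granges(out), intervals_to_granges(blacklist)
    )
    out <- out[n_hits == 0, ]
  }
  out
}
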
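#' Spike-in occupancy ratio
#'
#' Calibrated ChIP-seq adds a fixed fraction of spike-in chromatin (mouse, in
#' a human experiment) before immunoprecipitation. The occupancy ratio
#'
#' \deqn{OR = \frac{W_m \cdot IP_h}{W_h \cdot IP_m}}
#'
#' relates target-genome and spike-in read counts in the input (`wh`, `wm`)
#' and IP (`iph`, `ipm`) fractions, and rescales coverage so that occupancy
#' is comparable across conditions. OR is invariant under joint rescaling of
#' all four counts, and swapping the two genomes inverts it.
#'
#' @param counts Data frame with columns `wh`, `wm`, `iph`, `ipm`
#'   (non-negative read counts; one row per sample/condition).
#' @return `counts` with an `or` column appended.
#' @examples
#' occupancy_ratio(tibble::tibble(wh = 400, wm = 100, iph = 200, ipm = 50))
#' @export
occupancy_ratio <- function(counts) {
  assert_cols(counts, c("wh", "wm", "iph", "ipm"), "calibration counts")
  counts <- as_tibble(counts)
  for (col in c("wh", "wm", "iph", "ipm")) {
    if (any(counts[[col]] < 0)) abort(sprintf("`%s` must be non-negative", col))
  }
  zero_wh <- counts$wh == 0
  zero_ipm <- counts$ipm == 0
  if (any(zero_wh)) {
    abort(sprintf("occupancy ratio undefined: `wh` is zero in row(s) %s",
                  paste(which(zero_wh), collapse = ", ")))
  }
  if (any(zero_ipm)) {
    abort(sprintf("occupancy ratio undefined: `ipm` is zero in row(s) %s",
                  paste(which(zero_ipm), collapse = ", ")))
  }
  counts |>
    mutate(or = (as.numeric(.data$wm) * as.numeric(.data$iph)) /
             (as.numeric(.data$wh) * as.numeric(.data$ipm)))
}

#' Calibrate a coverage track with spike-in counts
#'
#' Coverage is first normalized to mean 1 over its covered bins (removing
#' sequencing depth), then multiplied by the [occupancy_ratio()] of the
#' sample, putting profiles from different conditions on a common
#' occupancy scale.
#'
#' @param coverage Data frame with a `value` column (plus any bin coordinate
#'   columns, e.g. `chrom`, `start`, `end` as in a bedGraph).
#' @param counts One-row data frame of calibration counts (see
#'   [occupancy_ratio()]).
#' @return `coverage` with `value` replaced by the calibrated signal.
#' @export
calibrate_coverage <- function(coverage, counts) {
  assert_cols(coverage, "value", "coverage")
  if (any(coverage$value < 0)) abort("coverage must be non-negative")
  m <- mean(coverage$value)
  if (!is.finite(m) || m == 0) abort("coverage is all zero; cannot normalize")
  or <- occupancy_ratio(counts)$or
  if (length(or) != 1) abort("`counts` must have exactly one row")
  as_tibble(coverage) |> mutate(value = .data$value / m * or)
}

#' Per-peak log2 fold change between two calibrated signals
#'
#' Averages each calibrated signal over the bins overlapping every peak and
#' reports `log2((mean_a + pseudocount) / (mean_b + pseudocount))`. Both
#' signals must be on the identical bin grid. Peaks covered by no bin get a
#' mean of zero on both sides and hence a log2 fold change of 0.
#'
#' @param signal_a,signal_b Data frames with `chrom`, `start`, `end`,
#'   `value` on the same grid (e.g. from [calibrate_coverage()]).
#' @param peaks Data frame of peak intervals (`chrom`, `start`, `end`).
#' @param pseudocount Positive stabilizer on the calibrated scale.
#' @return `peaks` with `mean_a`, `mean_b` and `log2fc` columns appended.
#' @export
peak_log2fc <- function(signal_a, signal_b, peaks, pseudocount = 0.1) {
  for (s in list(signal_a, signal_b)) {
    assert_cols(s, c("chrom", "start", "end", "value"), "signal")
  }
  if (pseudocount <= 0) abort("pseudocount must be positive")
  same_grid <- nrow(signal_a) == nrow(signal_b) &&
    identical(signal_a$chrom, signal_b$chrom) &&
    identical(signal_a$start, signal_b$start) &&
    identical(signal_a$end, signal_b$end)
  if (!same_grid) abort("signal_a and signal_b are not on the same bin grid")
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  peaks <- as_tibble(peaks)

  mean_over_peaks <- function(signal) {
    out <- rep(0, nrow(peaks))
    ov <- overlap_pairs(peaks, signal)
    if (nrow(ov) > 0) {
      agg <- ov |>
        mutate(value = signal$value[.data$subject_idx]) |>
        group_by(.data$query_idx) |>
        summarise(m = mean(.data$value), .groups = "drop")
      out[agg$query_idx] <- agg$m
    }
    out
  }
  peaks |>
    mutate(
      mean_a = mean_over_peaks(signal_a),
      mean_b = mean_over_peaks(signal_b),
      log2fc = log2((.data$mean_a + pseudocount) / (.data$mean_b + pseudocount))
    )
}
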
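#' Simulate spike-in calibration read counts
#'
#' Draws the four read-count totals of a calibrated ChIP experiment (input
#' and IP fractions, target and spike-in genome) as independent Poisson
#' counts parameterized so that the occupancy-ratio estimator recovers the
#' planted ratio in expectation: `wh ~ Pois(depth)`,
#' `wm, ipm ~ Pois(spike_frac * depth)` and `iph ~ Pois(or_true * depth)`.
#'
#' @param or_true Planted occupancy ratio(s); one row is drawn per element,
#'   names become the `condition` column.
#' @param depth Expected target-genome input depth (> 0).
#' @param spike_frac Spike-in chromatin fraction (default 5%).
#' @param seed Integer seed.
#' @return Tibble (`condition`, `wh`, `wm`, `iph`, `ipm`, `or_true`).
#' @export
simulate_chip_counts <- function(or_true = 1.5, depth = 1e6,
                                 spike_frac = 0.05, seed = 1L) {
  if (depth <= 0) abort("depth must be positive")
  if (any(or_true <= 0)) abort("or_true must be positive")
  cond <- names(or_true) %||% paste0("cond", seq_along(or_true))
  withr::with_seed(as.integer(seed), {
    tibble(
      condition = cond,
      wh = rpois(length(or_true), depth),
      wm = rpois(length(or_true), spike_frac * depth),
      iph = rpois(length(or_true), or_true * depth),
      ipm = rpois(length(or_true), spike_frac * depth),
      or_true = unname(or_true)
    )
  })
}

#' Simulate a binned coverage track with fold enrichment at peaks
#'
#' Flat baseline coverage over a binned chromosome with a multiplicative
#' enrichment at every peak, optionally Poisson-distorted -- the input for
#' calibration and per-peak fold-change computations.
#'
#' @param peaks Peak intervals (`chrom`, `start`, `end`).
#' @param chrom_lens Named vector of chromosome lengths.
#' @param bin_size Track bin size in bp.
#' @param base Baseline coverage per bin.
#' @param peak_fold Enrichment multiple applied to bins overlapping a peak
#'   (length 1 or one per peak).
#' @param noise `"none"` for exact values, `"poisson"` for counts.
#' @param seed Integer seed (used for `"poisson"`).
#' @return Coverage tibble (`chrom`, `start`, `end`, `value`).
#' @export
simulate_coverage <- function(peaks, chrom_lens, bin_size = 100L, base = 10,
                              peak_fold = 1, noise = c("none", "poisson"),
                              seed = 1L) {
  noise <- match.arg(noise)
  assert_cols(peaks, c("chrom", "start", "end"), "peaks")
  grid <- imap(chrom_lens, function(len, ch) {
    starts <- seq(0L, len - 1L, by = bin_size)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + bin_size, len))
  }) |> list_rbind()
  value <- rep(base, nrow(grid))
  if (nrow(peaks) > 0) {
    fold <- rep_len(peak_fold, nrow(peaks))
    ov <- overlap_pairs(grid, as_tibble(peaks))
    value[ov$query_idx] <- base * fold[ov$subject_idx]
  }
  if (noise == "poisson") {
    value <- withr::with_seed(as.integer(seed), rpois(length(value), value))
  }
  grid |> mutate(value = value)
}
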
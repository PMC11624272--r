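#' Simulate a bin table
#'
#' Tiles chromosomes with fixed-size bins and marks bait bins. By default
#' baits are chosen only in the interior of each chromosome, at least
#' `interior_margin` bins from either end, so every bait row can reach the
#' full interaction range of [simulate_contact_maps()] on both sides.
#'
#' @param chrom_lens Named vector of chromosome lengths (bp).
#' @param bin_size Bin size in bp (3 kb by default).
#' @param bait_bins Explicit bait bin ids; overrides sampling.
#' @param n_baits Number of bait bins to sample per chromosome.
#' @param interior_margin Minimum distance (bins) between a sampled bait and
#'   a chromosome end.
#' @param seed Integer seed for bait sampling.
#' @return A [bin_table()].
#' @export
simulate_bins <- function(chrom_lens, bin_size = 3000L, bait_bins = NULL,
                          n_baits = 10L, interior_margin = 0L, seed = 1L) {
  bins <- imap(chrom_lens, function(len, ch) {
    starts <- seq(0L, len - 1L, by = bin_size)
    tibble(chrom = ch, start = as.integer(starts),
           end = as.integer(pmin(starts + bin_size, len)))
  }) |> list_rbind() |>
    mutate(bin_id = row_number(), is_bait = FALSE)
  if (is.null(bait_bins)) {
    bait_bins <- withr::with_seed(as.integer(seed), {
      spans <- bins |>
        group_by(.data$chrom) |>
        summarise(first_id = min(.data$bin_id), last_id = max(.data$bin_id),
                  .groups = "drop")
      unlist(map(seq_len(nrow(spans)), function(i) {
        lo <- spans$first_id[i] + interior_margin
        hi <- spans$last_id[i] - interior_margin
        if (hi < lo) abort("interior_margin leaves no candidate bait bins")
        sample(seq(lo, hi), min(n_baits, hi - lo + 1))
      }))
    })
  }
  bins$is_bait[bait_bins] <- TRUE
  bin_table(bins)
}

#' Simulate capture-style contact matrices with planted loops
#'
#' For every bait row, pixels are generated at all bin distances 1..
#' `max_range / bin_size` within the chromosome with expected count
#' `base * d^(-decay_exp)` -- a pure power-law distance decay. Planted loop
#' pixels are multiplied by their `fold` in the conditions where the loop is
#' present. With `noise = "poisson"` counts are Poisson draws around these
#' expectations; with `"none"` the expectations themselves are returned, so
#' the decay is exact and (for interior baits) observed/expected is exactly
#' 1 off the planted pixels.
#'
#' @param bins A [bin_table()]; only bait rows generate pixels (the capture
#'   geometry -- every stored pixel touches a bait).
#' @param loops Data frame with `bait_bin`, `oe_bin`, `fold` (>= 1) and one
#'   logical presence column per condition named `in_<condition>` (e.g.
#'   `in_WT`, `in_KO`).
#' @param conditions Condition names; one matrix is returned per condition.
#' @param decay_exp Power-law decay exponent (> 0).
#' @param base Expected count at distance 1 bin.
#' @param max_range Maximum interaction span in bp.
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed.
#' @return Named list of raw `contact_matrix` objects, one per condition.
#' @export
simulate_contact_maps <- function(bins, loops = NULL,
                                  conditions = c("WT", "KO"),
                                  decay_exp = 1, base = 100,
                                  max_range = 500000L,
                                  noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  if (decay_exp <= 0) abort("decay_exp must be positive")
  bins <- bin_table(bins)
  bs <- bin_size(bins)
  mr <- as.integer(max_range / bs)
  spans <- chrom_spans(bins)
  baits <- bins |> filter(.data$is_bait) |> left_join(spans, by = "chrom")
  if (nrow(baits) == 0) abort("bin table has no bait bins")

  # canonical pixel grid: all (bait, col) pairs within range, deduplicated
  offs <- c(seq(-mr, -1L), seq(1L, mr))
  b_rep <- rep(baits$bin_id, each = length(offs))
  col <- b_rep + rep(offs, times = nrow(baits))
  ok <- col >= rep(baits$first_id, each = length(offs)) &
    col <= rep(baits$last_id, each = length(offs))
  grid <- tibble(bin1_id = pmin(b_rep[ok], col[ok]),
                 bin2_id = pmax(b_rep[ok], col[ok])) |> distinct()
  grid <- grid |>
    mutate(d = .data$bin2_id - .data$bin1_id,
           mu = base * .data$d^(-decay_exp))

  if (!is.null(loops) && nrow(loops) > 0) {
    assert_cols(loops, c("bait_bin", "oe_bin", "fold"), "loops")
    if (any(loops$fold < 1)) abort("loop fold must be >= 1")
    n <- nrow(bins)
    if (any(loops$bait_bin < 1 | loops$bait_bin > n |
              loops$oe_bin < 1 | loops$oe_bin > n)) {
      abort("planted loop anchor outside the bin table")
    }
  }

  out <- withr::with_seed(as.integer(seed), {
    lapply(conditions, function(cond) {
      mu <- grid$mu
      if (!is.null(loops) && nrow(loops) > 0) {
        pcol <- paste0("in_", cond)
        assert_cols(loops, pcol, "loops")
        active <- loops[loops[[pcol]], , drop = FALSE]
        if (nrow(active) > 0) {
          key <- paste(pmin(active$bait_bin, active$oe_bin),
                       pmax(active$bait_bin, active$oe_bin))
          idx <- match(key, paste(grid$bin1_id, grid$bin2_id))
          if (anyNA(idx)) {
            abort("planted loop outside the generated pixel grid (check max_range and bait flags)")
          }
          mu[idx] <- mu[idx] * active$fold
        }
      }
      count <- if (noise == "poisson") rpois(length(mu), mu) else mu
      contact_matrix(bins,
                     tibble(bin1_id = grid$bin1_id, bin2_id = grid$bin2_id,
                            count = count) |> filter(count > 0),
                     condition = cond, normalized = "raw")
    })
  })
  names(out) <- conditions
  out
}

#' Simulate per-cell-line loop call tables
#'
#' Emits one ChiCAGO-style call table per cell line from planted loops:
#' each loop present in a line's condition is called with probability
#' `detect_prob`, with read counts drawn as `min_reads + NegBinom` and
#' scores as `min_score + 0.01 + Gamma` (heavy-tailed, always passing the
#' default robustness filter). Optionally appends `n_subthreshold` decoy
#' calls per line that fail the filter (half by reads, half by score,
#' including exact boundary records `n_reads = 4` and `score = 3`).
#'
#' @param loops Planted loops: `bait_bin`, `oe_bin` and logical presence
#'   columns `in_WT`, `in_KO` (per condition).
#' @param bins A [bin_table()] used to place decoy calls.
#' @param line_condition Named character vector mapping cell line to
#'   condition (default: P and WT are STAG2-proficient, KO1/KO2 deficient).
#' @param detect_prob Per-line detection probability in `[0, 1]`.
#' @param read_mu,read_size Negative-binomial parameters for extra reads.
#' @param score_shape,score_rate Gamma parameters for extra score.
#' @param n_subthreshold Decoy calls per line failing the filter.
#' @param seed Integer seed.
#' @return List with `calls` (tibble: `cell_line`, `bait_bin`, `oe_bin`,
#'   `n_reads`, `score`) and `truth` (planted loops with per-line emission
#'   flags `called_<line>`).
#' @export
simulate_loop_calls <- function(loops, bins,
                                line_condition = c(P = "WT", WT = "WT",
                                                   KO1 = "KO", KO2 = "KO"),
                                detect_prob = 1, read_mu = 15, read_size = 2,
                                score_shape = 2, score_rate = 0.5,
                                n_subthreshold = 0L, seed = 1L) {
  if (detect_prob < 0 || detect_prob > 1) abort("detect_prob must be in [0, 1]")
  assert_cols(loops, c("bait_bin", "oe_bin"), "loops")
  loops <- as_tibble(loops)
  bins <- bin_table(bins)
  withr::with_seed(as.integer(seed), {
    truth <- loops
    calls <- imap(line_condition, function(cond, line) {
      pcol <- paste0("in_", cond)
      assert_cols(loops, pcol, "loops")
      present <- loops[loops[[pcol]], , drop = FALSE]
      emitted <- present[runif(nrow(present)) < detect_prob, , drop = FALSE]
      called <- logical(nrow(loops))
      called[match(paste(emitted$bait_bin, emitted$oe_bin),
                   paste(loops$bait_bin, loops$oe_bin))] <- TRUE
      truth[[paste0("called_", line)]] <<- called
      n <- nrow(emitted)
      tibble(
        cell_line = rep(line, n),
        bait_bin = emitted$bait_bin,
        oe_bin = emitted$oe_bin,
        n_reads = 5L + rnbinom(n, size = read_size, mu = read_mu),
        score = 3.01 + rgamma(n, shape = score_shape, rate = score_rate)
      )
    }) |> list_rbind()
    if (n_subthreshold > 0) {
      decoys <- imap(line_condition, function(cond, line) {
        k <- n_subthreshold
        bait_pool <- bins$bin_id[bins$is_bait]
        bait <- sample(bait_pool, k, replace = TRUE)
        oe <- pmax(1L, bait - sample(1:20, k, replace = TRUE))
        low_reads <- seq_len(k) <= ceiling(k / 2)
        tibble(
          cell_line = rep(line, k),
          bait_bin = bait, oe_bin = oe,
          n_reads = ifelse(low_reads, 4L, 5L + rnbinom(k, size = read_size,
                                                       mu = read_mu)),
          score = ifelse(low_reads, 3.01 + rgamma(k, score_shape, score_rate),
                         3)  # boundary: score exactly 3 must be dropped
        )
      }) |> list_rbind()
      calls <- bind_rows(calls, decoys)
      attr(calls, "n_subthreshold_per_line") <- n_subthreshold
    }
    list(calls = calls, truth = truth)
  })
}
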
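#' Downsample raw contact matrices to matched on-target totals
#'
#' Capture Hi-C libraries differ in the number of reads hitting the capture
#' probes. To make conditions comparable, every matrix is subsampled without
#' replacement (at single-count granularity, via a multivariate
#' hypergeometric draw) so that its on-target total -- the summed counts of
#' pixels touching at least one bait bin -- equals the minimum on-target
#' total across the inputs, exactly. Off-target pixels are subsampled at the
#' same global rate. Pixel support never grows.
#'
#' @param matrices List of raw `contact_matrix` objects on identical bin
#'   tables, with integer counts.
#' @param seed Integer seed; the draw is deterministic per seed.
#' @return List of downsampled raw `contact_matrix` objects, same order.
#' @export
downsample_to_match <- function(matrices, seed = 1L) {
  if (length(matrices) < 2) abort("need at least two matrices to match")
  for (m in matrices) {
    if (!inherits(m, "contact_matrix")) abort("inputs must be contact_matrix objects")
    if (m$normalized != "raw") abort("downsampling requires raw matrices")
    if (!all(is_wholenumber(m$pixels$count))) {
      abort("downsampling requires integer counts")
    }
  }
  ref <- matrices[[1]]$bins
  for (m in matrices[-1]) {
    if (!identical(as.data.frame(m$bins[c("chrom", "start", "end", "bin_id", "is_bait")]),
                   as.data.frame(ref[c("chrom", "start", "end", "bin_id", "is_bait")]))) {
      abort("matrices are on different bin tables")
    }
  }
  is_bait <- ref$is_bait
  on_totals <- vapply(matrices, function(m) {
    on <- is_bait[m$pixels$bin1_id] | is_bait[m$pixels$bin2_id]
    sum(m$pixels$count[on])
  }, numeric(1))
  target <- min(on_totals)

  withr::with_seed(as.integer(seed), {
    lapply(matrices, function(m) {
      px <- m$pixels
      on <- is_bait[px$bin1_id] | is_bait[px$bin2_id]
      tot_on <- sum(px$count[on])
      rate <- if (tot_on > 0) target / tot_on else 0
      new_count <- px$count
      if (tot_on > target) {
        new_count[on] <- rmvhyper(px$count[on], target)
      } else if (tot_on == 0) {
        new_count[on] <- 0
      }
      tot_off <- sum(px$count[!on])
      if (tot_off > 0) {
        goal <- min(tot_off, round(rate * tot_off))
        new_count[!on] <- rmvhyper(px$count[!on], goal)
      }
      px$count <- new_count
      m$pixels <- px |> filter(.data$count > 0)
      m
    })
  })
}

#' Row-normalize a raw contact matrix
#'
#' Divides every row of the (symmetric) raw matrix by its row sum, so each
#' row with a positive sum sums to exactly 1; zero rows stay zero (they are
#' simply absent from the sparse output). Because row division breaks
#' symmetry, the result is stored row-oriented: one record per (row, column)
#' with both orientations of every off-diagonal pixel.
#'
#' @param m A raw `contact_matrix`.
#' @return A `contact_matrix` with `normalized = "row"`.
#' @export
row_normalize <- function(m) {
  if (!inherits(m, "contact_matrix")) abort("`m` must be a contact_matrix")
  if (m$normalized != "raw") {
    abort(sprintf("row_normalize() expects a raw matrix, got '%s'", m$normalized))
  }
  px <- m$pixels |> filter(.data$count > 0)
  sym <- bind_rows(
    px |> transmute(row_id = .data$bin1_id, col_id = .data$bin2_id,
                    value = .data$count),
    px |> filter(.data$bin1_id != .data$bin2_id) |>
      transmute(row_id = .data$bin2_id, col_id = .data$bin1_id,
                value = .data$count)
  )
  sym <- sym |>
    group_by(.data$row_id) |>
    mutate(value = .data$value / sum(.data$value)) |>
    ungroup() |>
    arrange(.data$row_id, .data$col_id)
  contact_matrix(m$bins, sym, condition = m$condition, normalized = "row")
}

#' Distance-decay (observed/expected) normalization over bait rows
#'
#' The expected value at bin distance d is the mean of row-normalized values
#' at distance d over bait rows only, computed per chromosome with zeros
#' counted at every position a bait row could reach within its chromosome.
#' Each bait-row pixel is divided by the expected value at its distance,
#' yielding an O/E matrix in which pure distance decay is flat at 1. Only
#' bait rows are retained (capture matrices carry no other rows);
#' inter-chromosomal pixels have no distance and are dropped with a warning.
#'
#' @param m A row-normalized `contact_matrix` (see [row_normalize()]).
#' @return A `contact_matrix` with `normalized = "row+decay"`; the per-
#'   chromosome expected-by-distance table is attached as attribute
#'   `"expected"`.
#' @export
decay_normalize <- function(m) {
  if (!inherits(m, "contact_matrix")) abort("`m` must be a contact_matrix")
  if (m$normalized != "row") {
    abort(sprintf("decay_normalize() expects a row-normalized matrix, got '%s'",
                  m$normalized))
  }
  bins <- m$bins
  if (!any(bins$is_bait)) abort("no bait rows in the bin table")
  chrom_of <- bins$chrom
  px <- m$pixels |>
    mutate(chrom = chrom_of[.data$row_id],
           trans = chrom_of[.data$col_id] != .data$chrom)
  if (any(px$trans)) {
    warn(sprintf("dropping %d inter-chromosomal pixel(s): no decay distance",
                 sum(px$trans)))
    px <- px |> filter(!.data$trans)
  }
  px <- px |>
    filter(bins$is_bait[.data$row_id]) |>
    mutate(d = abs(.data$col_id - .data$row_id))

  spans <- chrom_spans(bins)
  baits <- bins |>
    filter(.data$is_bait) |>
    left_join(spans, by = "chrom")

  # number of reachable (bait row, column) pairs at each distance, per chrom
  pair_counts <- function(chr, dists) {
    b <- baits |> filter(.data$chrom == chr)
    vapply(dists, function(d) {
      if (d == 0) return(as.numeric(nrow(b)))
      sum(b$bin_id - d >= b$first_id) + sum(b$bin_id + d <= b$last_id)
    }, numeric(1))
  }
  expected <- px |>
    group_by(.data$chrom, .data$d) |>
    summarise(total = sum(.data$value), .groups = "drop")
  expected <- expected |>
    group_by(.data$chrom) |>
    mutate(n_pairs = pair_counts(.data$chrom[1], .data$d)) |>
    ungroup() |>
    mutate(expected = .data$total / .data$n_pairs)

  out <- px |>
    left_join(expected |> select("chrom", "d", "expected"),
              by = c("chrom", "d")) |>
    mutate(value = .data$value / .data$expected) |>
    select("row_id", "col_id", "value")
  res <- contact_matrix(m$bins, out, condition = m$condition,
                        normalized = "row+decay")
  attr(res, "expected") <- expected
  res
}

#' Read loop strengths off an O/E matrix
#'
#' Loop strength is the observed/expected value at the loop's single 3-kb
#' pixel, read in the bait -> other-end orientation; absent pixels have
#' strength 0. A window half-width in bins can be supplied to average a
#' small square around the pixel instead.
#'
#' @param m A `contact_matrix` with `normalized = "row+decay"`.
#' @param loops Data frame with `bait_bin` and `oe_bin` columns.
#' @param window Half-width, in bins, of the square window averaged around
#'   the loop pixel (0 = the single pixel, the default).
#' @return `loops` with a `strength` column appended.
#' @export
loop_strength <- function(m, loops, window = 0L) {
  if (!inherits(m, "contact_matrix") || m$normalized != "row+decay") {
    abort("loop_strength() expects an O/E (row+decay) contact_matrix")
  }
  assert_cols(loops, c("bait_bin", "oe_bin"), "loops")
  loops <- as_tibble(loops)
  n <- nrow(m$bins)
  if (nrow(loops) > 0 &&
      any(loops$bait_bin < 1 | loops$bait_bin > n |
            loops$oe_bin < 1 | loops$oe_bin > n)) {
    abort("loop anchor outside the bin table")
  }
  px <- m$pixels
  if (window == 0) {
    out <- loops |>
      left_join(px, by = c(bait_bin = "row_id", oe_bin = "col_id")) |>
      mutate(strength = coalesce(.data$value, 0)) |>
      select(-"value")
  } else {
    offs <- expand_grid(di = -window:window, dj = -window:window)
    out <- loops |>
      mutate(.loop = row_number()) |>
      cross_join(offs) |>
      mutate(row_id = .data$bait_bin + .data$di,
             col_id = .data$oe_bin + .data$dj) |>
      filter(.data$row_id >= 1, .data$row_id <= n,
             .data$col_id >= 1, .data$col_id <= n) |>
      left_join(px, by = c("row_id", "col_id")) |>
      group_by(.data$.loop) |>
      summarise(strength = mean(coalesce(.data$value, 0)), .groups = "drop") |>
      right_join(loops |> mutate(.loop = row_number()), by = ".loop") |>
      arrange(.data$.loop) |>
      select(-".loop") |>
      relocate("strength", .after = last_col())
  }
  out
}

#' Differential loop strength between two conditions
#'
#' Computes `log2((s_ko + eps) / (s_wt + eps))` per loop, where the
#' pseudocount `eps` defaults to 10% of the median positive strength pooled
#' across both conditions (so the comparison is stable when one side is 0).
#'
#' @param m_wt,m_ko O/E `contact_matrix` objects for the two conditions.
#' @param loops Data frame with `bait_bin`, `oe_bin`.
#' @param pseudocount Optional explicit pseudocount; `NULL` uses the 10%%-of-
#'   median rule.
#' @inheritParams loop_strength
#' @return `loops` with `strength_wt`, `strength_ko` and `delta_log2`.
#' @export
loop_strength_change <- function(m_wt, m_ko, loops, pseudocount = NULL,
                                 window = 0L) {
  s_wt <- loop_strength(m_wt, loops, window = window)$strength
  s_ko <- loop_strength(m_ko, loops, window = window)$strength
  pooled <- c(s_wt, s_ko)
  pos <- pooled[pooled > 0]
  eps <- pseudocount %||% if (length(pos) > 0) 0.1 * median(pos) else 1
  as_tibble(loops) |>
    mutate(strength_wt = s_wt, strength_ko = s_ko,
           delta_log2 = log2((s_ko + eps) / (s_wt + eps)))
}
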
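#' Filter loop calls on read support and score
#'
#' Keeps calls with at least `min_reads` supporting reads (inclusive) and a
#' score strictly greater than `min_score` -- the robustness criterion used
#' for capture Hi-C interaction calls (five reads, score above 3).
#'
#' @param calls Data frame with `n_reads` and `score` columns.
#' @param min_reads Minimum read count (kept when `n_reads >= min_reads`).
#' @param min_score Score threshold (kept when `score > min_score`).
#' @return Filtered tibble.
#' @export
filter_loop_calls <- function(calls, min_reads = 5L, min_score = 3) {
  assert_cols(calls, c("n_reads", "score"), "loop calls")
  as_tibble(calls) |>
    filter(.data$n_reads >= min_reads, .data$score > min_score)
}

#' Presence pattern of loops across cell lines
#'
#' Collapses a long call table (one row per call per cell line) into one row
#' per loop identity -- exact (`bait_bin`, `oe_bin`) equality on the shared
#' bin grid -- with one logical presence column per cell line.
#'
#' @param calls Data frame with `bait_bin`, `oe_bin`, `cell_line`.
#' @param cell_lines Required cell lines, in presence-column order. An error
#'   is raised when one of them has no calls at all.
#' @return Tibble with `bait_bin`, `oe_bin` and `in_<line>` logical columns.
#' @export
loop_presence <- function(calls, cell_lines = c("P", "WT", "KO1", "KO2")) {
  assert_cols(calls, c("bait_bin", "oe_bin", "cell_line"), "loop calls")
  missing <- setdiff(cell_lines, unique(calls$cell_line))
  if (length(missing) > 0) {
    abort(sprintf("no calls for cell line(s): %s", paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(unique(calls$cell_line), cell_lines)
  if (length(unknown) > 0) {
    abort(sprintf("unexpected cell line(s): %s", paste(unknown, collapse = ", ")))
  }
  wide <- as_tibble(calls) |>
    distinct(.data$bait_bin, .data$oe_bin, .data$cell_line) |>
    mutate(.present = TRUE,
           cell_line = factor(.data$cell_line, levels = cell_lines)) |>
    pivot_wider(names_from = "cell_line", values_from = ".present",
                names_prefix = "in_", values_fill = FALSE,
                names_expand = TRUE) |>
    arrange(.data$bait_bin, .data$oe_bin)
  wide
}

#' Condition consensus sets of loops
#'
#' The robust interaction sets are defined per condition: a loop is in the
#' proficient (WT) set when called in *both* STAG2-proficient lines, and in
#' the deficient (KO) set when called in *both* KO clones.
#'
#' @param presence Output of [loop_presence()].
#' @param proficient,deficient Names of the two cell lines of each condition.
#' @return `presence` with logical `in_wt_set` and `in_ko_set` columns.
#' @export
consensus_loops <- function(presence,
                            proficient = c("P", "WT"),
                            deficient = c("KO1", "KO2")) {
  pro_cols <- paste0("in_", proficient)
  def_cols <- paste0("in_", deficient)
  assert_cols(presence, c("bait_bin", "oe_bin", pro_cols, def_cols), "presence")
  presence |>
    mutate(
      in_wt_set = .data[[pro_cols[1]]] & .data[[pro_cols[2]]],
      in_ko_set = .data[[def_cols[1]]] & .data[[def_cols[2]]]
    )
}

#' Classify a 4-line presence pattern
#'
#' Pure vectorized function of the presence pattern over (P, WT, KO1, KO2):
#' called in at least 3 of the 4 lines -> `"common"`; called only in the two
#' STAG2-expressing lines -> `"lost"`; called only in the two KO clones ->
#' `"gained"`; every other pattern -> `"unclassified"`.
#'
#' @param in_p,in_wt,in_ko1,in_ko2 Logical vectors.
#' @return Character vector of labels.
#' @export
classify_loop_pattern <- function(in_p, in_wt, in_ko1, in_ko2) {
  n_called <- in_p + in_wt + in_ko1 + in_ko2
  case_when(
    n_called >= 3 ~ "common",
    in_p & in_wt & !in_ko1 & !in_ko2 ~ "lost",
    !in_p & !in_wt & in_ko1 & in_ko2 ~ "gained",
    TRUE ~ "unclassified"
  )
}

#' Classify consensus loops as common / gained / lost
#'
#' Restricts to the union of the two consensus sets, labels each loop from
#' its presence pattern (see [classify_loop_pattern()]) and measures its
#' length as the distance between anchor-bin midpoints.
#'
#' @param calls Long call table (`bait_bin`, `oe_bin`, `cell_line`), already
#'   filtered with [filter_loop_calls()].
#' @param bins A [bin_table()] used for loop lengths.
#' @inheritParams loop_presence
#' @inheritParams consensus_loops
#' @return Tibble with one row per consensus loop: presence columns, set
#'   flags, `label` and `length_bp` (NA for inter-chromosomal pairs).
#' @export
classify_loops <- function(calls, bins,
                           cell_lines = c("P", "WT", "KO1", "KO2"),
                           proficient = c("P", "WT"),
                           deficient = c("KO1", "KO2")) {
  bins <- bin_table(bins)
  pres <- loop_presence(calls, cell_lines) |>
    consensus_loops(proficient, deficient) |>
    filter(.data$in_wt_set | .data$in_ko_set)
  mid <- bin_midpoints(bins)
  same_chrom <- bins$chrom[pres$bait_bin] == bins$chrom[pres$oe_bin]
  pres |>
    mutate(
      label = classify_loop_pattern(
        .data[[paste0("in_", cell_lines[1])]],
        .data[[paste0("in_", cell_lines[2])]],
        .data[[paste0("in_", cell_lines[3])]],
        .data[[paste0("in_", cell_lines[4])]]
      ),
      length_bp = ifelse(same_chrom,
                         abs(mid[.data$oe_bin] - mid[.data$bait_bin]),
                         NA_real_)
    )
}

#' Loop-length histogram over size strata
#'
#' Counts loops per length stratum, optionally split by a grouping column
#' (condition, label, ...). Default strata follow the sizes discussed for
#' cohesin-mediated loops: below 80 kb, 80-800 kb, 800 kb - 1 Mb, above 1 Mb.
#'
#' @param loops Data frame with a `length_bp` column.
#' @param by Optional grouping column (tidy-eval), e.g. `label`.
#' @param breaks Increasing break points in bp, implicitly spanning
#'   `[breaks[1], Inf)`.
#' @return Tibble of counts per (group,) stratum, with zero-count strata
#'   retained.
#' @export
loop_length_profile <- function(loops, by = NULL,
                                breaks = c(0, 80e3, 800e3, 1e6, Inf)) {
  assert_cols(loops, "length_bp", "loops")
  if (is.unsorted(breaks, strictly = TRUE)) abort("breaks must be increasing")
  by_quo <- enquo(by)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  labs <- paste0("[", fmt(head(breaks, -1)), ",", fmt(breaks[-1]), ")")
  dat <- as_tibble(loops) |>
    filter(!is.na(.data$length_bp)) |>
    mutate(stratum = cut(.data$length_bp, breaks = breaks, labels = labs,
                         right = FALSE, include.lowest = FALSE))
  if (quo_is_null(by_quo)) {
    dat |> count(.data$stratum, .drop = FALSE, name = "n")
  } else {
    dat |> count(!!by_quo, .data$stratum, .drop = FALSE, name = "n")
  }
}
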
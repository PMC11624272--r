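#' Anchor-centered local pileup of an O/E contact matrix
#'
#' Aggregates observed/expected signal in a local window centered on the
#' diagonal at each anchor bin: element (i, j) of the output is the mean
#' over anchors of the O/E value at (anchor + i, anchor + j), for offsets
#' up to `pad` bp on each side. Missing pixels count as 1 (the expected
#' value) rather than 0, because sparse capture matrices are zero-dominated
#' and zero imputation would bias means downward. Windows that cross a
#' chromosome end are dropped entirely. Stored pixels are symmetrized (mean
#' of the two orientations where both exist) before lookup.
#'
#' @param m A `contact_matrix` with `normalized = "row+decay"`.
#' @param anchors Integer vector of anchor bin ids.
#' @param pad Half-window in bp (default 500 kb); must be a multiple of the
#'   bin size.
#' @param scale `"linear"` or `"log2"` (log2 applied last, to the mean).
#' @return A numeric matrix of side `2 * pad / bin_size + 1`, class
#'   `contact_pileup`, with attributes `n_anchors` (anchors actually used),
#'   `pad`, `bin_size` and `scale`.
#' @export
local_pileup <- function(m, anchors, pad = 500000,
                         scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!inherits(m, "contact_matrix") || m$normalized != "row+decay") {
    abort("local_pileup() expects an O/E (row+decay) contact_matrix")
  }
  bs <- bin_size(m)
  if (pad %% bs != 0) abort("pad must be a multiple of the bin size")
  w <- as.integer(pad / bs)
  side <- 2L * w + 1L
  bins <- m$bins
  anchors <- as.integer(anchors)
  if (length(anchors) == 0) abort("no anchors supplied")
  if (any(anchors < 1 | anchors > nrow(bins))) abort("anchor outside bin table")

  spans <- chrom_spans(bins)
  lims <- bins |>
    select("bin_id", "chrom") |>
    left_join(spans, by = "chrom")
  ok <- anchors - w >= lims$first_id[anchors] & anchors + w <= lims$last_id[anchors]
  used <- anchors[ok]
  if (length(used) == 0) abort("no usable anchors: all windows cross a chromosome end")

  # symmetrize stored O/E pixels
  px <- m$pixels
  off_diag <- px[px$row_id != px$col_id, ]
  pair <- bind_rows(
    px,
    tibble(row_id = off_diag$col_id, col_id = off_diag$row_id,
           value = off_diag$value)
  ) |>
    group_by(.data$row_id, .data$col_id) |>
    summarise(value = mean(.data$value), .groups = "drop")

  acc <- matrix(0, side, side)
  for (a in used) {
    sub <- pair |>
      filter(.data$row_id >= a - w, .data$row_id <= a + w,
             .data$col_id >= a - w, .data$col_id <= a + w)
    if (nrow(sub) > 0) {
      i <- sub$row_id - a + w + 1L
      j <- sub$col_id - a + w + 1L
      # accumulate deviations from the expected value of 1
      dev <- rowsum(sub$value - 1, group = (j - 1L) * side + i)
      idx <- as.integer(rownames(dev))
      acc[idx] <- acc[idx] + dev[, 1]
    }
  }
  out <- 1 + acc / length(used)
  if (scale == "log2") out <- log2(out)
  offsets <- seq(-w, w) * bs
  dimnames(out) <- list(offsets, offsets)
  structure(out, class = c("contact_pileup", "matrix"),
            n_anchors = length(used), pad = pad, bin_size = bs, scale = scale)
}

#' Pileups stratified by repeat class and cohesin status
#'
#' Runs [local_pileup()] once per stratum of an anchor table, typically the
#' (repeat length class) x (cohesin bound or not) strata used for EWS::FLI1
#' binding sites. Empty or unusable strata are reported with `n_anchors = 0`
#' and a `NULL` pileup rather than failing.
#'
#' @param m A `contact_matrix` with `normalized = "row+decay"`.
#' @param anchor_table Data frame with `bin_id` plus the stratifying columns.
#' @param ... Stratifying columns (tidy-eval), e.g. `repeat_class, cohesin`.
#' @inheritParams local_pileup
#' @return Tibble with the stratum columns, `n_anchors`, and a `pileup`
#'   list-column of `contact_pileup` matrices.
#' @export
stratified_pileups <- function(m, anchor_table, ..., pad = 500000,
                               scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  assert_cols(anchor_table, "bin_id", "anchor table")
  grps <- as_tibble(anchor_table) |>
    group_by(...) |>
    summarise(bin_ids = list(.data$bin_id), .groups = "drop")
  if (nrow(grps) == 0) abort("anchor table is empty")
  grps |>
    mutate(
      pileup = map(.data$bin_ids, function(ids) {
        tryCatch(local_pileup(m, ids, pad = pad, scale = scale),
                 error = function(e) NULL)
      }),
      n_anchors = vapply(.data$pileup, function(p) {
        if (is.null(p)) 0L else attr(p, "n_anchors")
      }, integer(1))
    ) |>
    select(-"bin_ids") |>
    relocate("n_anchors", .before = "pileup")
}

#' Tidy a pileup matrix into offset/value rows
#' @param x A `contact_pileup`.
#' @param ... Unused.
#' @return Tibble with `offset1`, `offset2` (bp) and `value`.
#' @export
tidy.contact_pileup <- function(x, ...) {
  offsets <- as.numeric(rownames(x))
  expand_grid(offset1 = offsets, offset2 = offsets) |>
    arrange(.data$offset2, .data$offset1) |>
    mutate(value = as.vector(unclass(x)))
}

#' Heatmap of a local pileup
#' @param object A `contact_pileup`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_pileup <- function(object, ...) {
  dat <- tidy(object)
  lab <- if (attr(object, "scale") == "log2") "O/E (log2)" else "O/E"
  ggplot(dat, aes(x = .data$offset1 / 1e3, y = .data$offset2 / 1e3,
                  fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         midpoint = if (attr(object, "scale") == "log2") 0 else 1,
                         name = lab) +
    coord_fixed() +
    labs(x = "offset (kb)", y = "offset (kb)",
         subtitle = sprintf("n = %d anchors", attr(object, "n_anchors"))) +
    theme_minimal()
}
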
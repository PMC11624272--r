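#' Bin table constructor/validator
#'
#' A bin table tiles each chromosome with fixed-size bins (3 kb by default in
#' promoter capture Hi-C work) and flags the bins that contain a capture
#' "bait" (promoter) fragment. Bin ids must be dense, sorted, and 1-based, so
#' that within a chromosome the difference of two bin ids is their distance
#' in bins.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), `bin_id` (dense 1..n, sorted) and `is_bait` (logical).
#' @return The validated bin table as a tibble with a `bin_size` attribute.
#' @export
bin_table <- function(bins) {
  assert_cols(bins, c("chrom", "start", "end", "bin_id", "is_bait"), "bin table")
  bins <- as_tibble(bins)
  bins$bin_id <- as.integer(bins$bin_id)
  bins$is_bait <- as.logical(bins$is_bait)
  if (!identical(bins$bin_id, seq_len(nrow(bins)))) {
    abort("bin_ids must be dense, sorted and start at 1")
  }
  widths <- bins$end - bins$start
  if (any(widths <= 0)) abort("bins must have positive width")
  # bins of one chromosome must be contiguous and non-overlapping
  by_chrom <- split(seq_len(nrow(bins)), bins$chrom)
  for (idx in by_chrom) {
    if (any(diff(idx) != 1L)) abort("bins of one chromosome must be consecutive")
    if (any(bins$start[idx][-1] != bins$end[idx][-length(idx)])) {
      abort("bins must tile each chromosome without gaps or overlap")
    }
  }
  attr(bins, "bin_size") <- as.integer(max(widths))
  bins
}

#' Sparse binned contact matrix
#'
#' Container for symmetric binned Hi-C / capture Hi-C counts. Raw pixels are
#' stored canonically (`bin1_id <= bin2_id`, column `count`); after
#' normalization the matrix is row-oriented (`row_id`, `col_id`, `value`)
#' because row normalization is not symmetric. The normalization state is
#' recorded and checked by every operation.
#'
#' @param bins A [bin_table()].
#' @param pixels Pixel table: `bin1_id`, `bin2_id`, `count` for raw matrices,
#'   `row_id`, `col_id`, `value` otherwise. Raw pixels are canonicalized.
#' @param condition Free-form condition label (e.g. `"WT"`, `"KO"`).
#' @param normalized One of `"raw"`, `"row"`, `"row+decay"`.
#' @return An object of class `contact_matrix`.
#' @examples
#' bins <- bin_table(tibble::tibble(
#'   chrom = "chr1", start = c(0, 3000, 6000), end = c(3000, 6000, 9000),
#'   bin_id = 1:3, is_bait = c(TRUE, FALSE, FALSE)
#' ))
#' cm <- contact_matrix(bins, tibble::tibble(
#'   bin1_id = 1L, bin2_id = c(2L, 3L), count = c(10, 4)
#' ), condition = "WT")
#' @export
contact_matrix <- function(bins, pixels,
                           condition = NA_character_,
                           normalized = c("raw", "row", "row+decay")) {
  normalized <- match.arg(normalized)
  bins <- bin_table(bins)
  pixels <- as_tibble(pixels)
  n <- nrow(bins)
  if (normalized == "raw") {
    assert_cols(pixels, c("bin1_id", "bin2_id", "count"), "pixel table")
    if (any(pixels$count < 0)) abort("pixel counts must be non-negative")
    bad <- pixels$bin1_id < 1 | pixels$bin2_id < 1 |
      pixels$bin1_id > n | pixels$bin2_id > n
    if (any(bad)) abort("pixel bin ids outside the bin table")
    flip <- pixels$bin1_id > pixels$bin2_id
    if (any(flip)) {
      tmp <- pixels$bin1_id[flip]
      pixels$bin1_id[flip] <- pixels$bin2_id[flip]
      pixels$bin2_id[flip] <- tmp
    }
    pixels <- pixels |>
      group_by(.data$bin1_id, .data$bin2_id) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      arrange(.data$bin1_id, .data$bin2_id)
  } else {
    assert_cols(pixels, c("row_id", "col_id", "value"), "pixel table")
    if (any(pixels$row_id < 1 | pixels$row_id > n |
              pixels$col_id < 1 | pixels$col_id > n)) {
      abort("pixel bin ids outside the bin table")
    }
  }
  structure(
    list(bins = bins, pixels = pixels,
         condition = condition, normalized = normalized),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s: %d bins (%d bait), %d pixels, %s, %s normalized\n",
    x$condition %||% "?", nrow(x$bins), sum(x$bins$is_bait),
    nrow(x$pixels), paste0(bin_size(x), " bp bins"), x$normalized
  ))
  invisible(x)
}

#' Bin size of a contact matrix or bin table
#' @param x A `contact_matrix` or bin table.
#' @return Bin size in bp.
#' @export
bin_size <- function(x) {
  if (inherits(x, "contact_matrix")) x <- x$bins
  as.integer(attr(x, "bin_size") %||% max(x$end - x$start))
}

#' Tidy a contact matrix into a pixel-level tibble
#'
#' Joins genomic coordinates of both anchors onto the pixel table.
#'
#' @param x A `contact_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per stored pixel.
#' @export
tidy.contact_matrix <- function(x, ...) {
  b <- x$bins |> select("chrom", "start", "end", "bin_id")
  if (x$normalized == "raw") {
    x$pixels |>
      left_join(b, by = c(bin1_id = "bin_id")) |>
      rename(chrom1 = "chrom", start1 = "start", end1 = "end") |>
      left_join(b, by = c(bin2_id = "bin_id")) |>
      rename(chrom2 = "chrom", start2 = "start", end2 = "end")
  } else {
    x$pixels |>
      left_join(b, by = c(row_id = "bin_id")) |>
      rename(chrom1 = "chrom", start1 = "start", end1 = "end") |>
      left_join(b, by = c(col_id = "bin_id")) |>
      rename(chrom2 = "chrom", start2 = "start", end2 = "end")
  }
}

# bin midpoints (bp), indexed by bin_id
bin_midpoints <- function(bins) {
  (bins$start + bins$end) / 2
}

# first/last bin id per chromosome, as a lookup tibble
chrom_spans <- function(bins) {
  bins |>
    group_by(.data$chrom) |>
    summarise(first_id = min(.data$bin_id), last_id = max(.data$bin_id),
              .groups = "drop")
}
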
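#' @import dplyr
#' @import tidyr
#' @import ggplot2
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dfr map2 imap pmap list_rbind
#' @importFrom rlang abort warn inform %||% .data enquo quo_is_null eval_tidy
#' @importFrom stringr str_c str_detect str_locate_all str_sub str_sub<-
#' @importFrom stats rpois rnbinom rgamma rbinom rexp runif rnorm rhyper
#' @importFrom stats median quantile prcomp kruskal.test wilcox.test uniroot
#' @importFrom stats setNames sd
#' @importFrom utils head
NULL

# Fail unless all `cols` are present in `df`.
assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

#' Convert a 0-based half-open interval table to GRanges
#'
#' @param x Data frame with `chrom`, `start`, `end` (BED convention:
#'   0-based, half-open).
#' @return A [GenomicRanges::GRanges] (1-based, closed).
#' @keywords internal
#' @noRd
intervals_to_granges <- function(x) {
  assert_cols(x, c("chrom", "start", "end"))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# >=1 bp overlap between two 0-based half-open interval tables; returns a
# tibble of (query_idx, subject_idx) pairs.
overlap_pairs <- function(query, subject) {
  # disjoint sequence names are a legitimate "no overlap", not a warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_granges(query), intervals_to_granges(subject)
  ))
  tibble(
    query_idx = S4Vectors::queryHits(hits),
    subject_idx = S4Vectors::subjectHits(hits)
  )
}

# Multivariate hypergeometric draw: sample `k` units without replacement
# from urns with integer contents `counts`. Returns per-urn draws.
rmvhyper <- function(counts, k) {
  counts <- as.integer(round(counts))
  n <- length(counts)
  out <- integer(n)
  rem <- sum(counts)
  if (k > rem) abort("cannot draw more units than are available")
  for (i in seq_len(n)) {
    if (k <= 0) break
    ci <- counts[i]
    x <- rhyper(1, ci, rem - ci, k)
    out[i] <- x
    k <- k - x
    rem <- rem - ci
  }
  out
}
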
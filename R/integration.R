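#' Select direct EWS::FLI1 target genes from a knock-down contrast
#'
#' Direct targets are genes deregulated after EWS::FLI1 knock-down with
#' `|log2fc| > lfc_min` (strict), the screen applied before integrating
#' occupancy and contact evidence.
#'
#' @param deg Data frame with `gene_id` and `log2fc`.
#' @param lfc_min Absolute log2 fold-change threshold (exclusive).
#' @return Filtered tibble of responsive genes.
#' @export
select_direct_targets <- function(deg, lfc_min = 0.5) {
  assert_cols(deg, c("gene_id", "log2fc"), "contrast table")
  as_tibble(deg) |> filter(abs(.data$log2fc) > lfc_min)
}

#' Map gene promoters to their bait bins
#'
#' The promoter is taken as TSS +/- `promoter_pad` bp unless the annotation
#' carries explicit `promoter_start`/`promoter_end` columns. Bait bins are
#' all bins overlapping the promoter interval.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `tss` (0-based position)
#'   or explicit `promoter_start`/`promoter_end`.
#' @param bins A [bin_table()].
#' @param promoter_pad Promoter half-width in bp around the TSS.
#' @return Tibble (`gene_id`, `bait_bin`); genes whose promoter overlaps no
#'   bin are absent (with a warning).
#' @export
gene_bait_bins <- function(genes, bins, promoter_pad = 2000) {
  assert_cols(genes, c("gene_id", "chrom"), "genes")
  bins <- bin_table(bins)
  genes <- as_tibble(genes)
  if (!all(c("promoter_start", "promoter_end") %in% names(genes))) {
    assert_cols(genes, "tss", "genes")
    genes <- genes |>
      mutate(promoter_start = pmax(0, .data$tss - promoter_pad),
             promoter_end = .data$tss + promoter_pad)
  }
  prom <- genes |>
    transmute(.data$gene_id, .data$chrom,
              start = .data$promoter_start, end = .data$promoter_end)
  ov <- overlap_pairs(prom, bins)
  out <- ov |>
    transmute(gene_id = prom$gene_id[.data$query_idx],
              bait_bin = bins$bin_id[.data$subject_idx]) |>
    distinct()
  missing <- setdiff(genes$gene_id, out$gene_id)
  if (length(missing) > 0) {
    warn(sprintf("%d gene(s) have no bait bin: %s", length(missing),
                 paste(head(missing, 5), collapse = ", ")))
  }
  out
}

#' Relevant promoter loops per gene
#'
#' Joins classified loops onto genes through their bait bins: a loop is
#' relevant to a gene when its bait anchor falls in one of the gene's
#' promoter bins. Loops are pooled across a gene's baits.
#'
#' @param genes Gene annotation (see [gene_bait_bins()]).
#' @param loops Classified loop table (from [classify_loops()]), with
#'   `bait_bin`, `oe_bin` and `label`.
#' @param bins A [bin_table()].
#' @inheritParams gene_bait_bins
#' @return Tibble with one row per (gene, loop) pair.
#' @export
gene_loops <- function(genes, loops, bins, promoter_pad = 2000) {
  assert_cols(loops, c("bait_bin", "oe_bin"), "loops")
  gb <- gene_bait_bins(genes, bins, promoter_pad)
  gb |>
    inner_join(as_tibble(loops), by = "bait_bin",
               relationship = "many-to-many")
}

#' Assign genes to enhancer-contact classes
#'
#' Replicates the gene grouping used to read EWS::FLI1 regulation off the
#' promoter interactome: class `P` when a GGAA-bearing peak (`best_n >= 1`)
#' overlaps the gene promoter; otherwise `distal_long` when at least one
#' classified loop links a promoter bait bin to a bin holding a long-repeat
#' peak (`best_n > 4`); otherwise `distal_short` for short-repeat peak bins;
#' otherwise `none`. Precedence is P > distal_long > distal_short.
#'
#' @param genes Gene annotation (see [gene_bait_bins()]).
#' @param peaks Annotated peaks (from [annotate_peaks()], with `best_n` and
#'   `repeat_class`).
#' @param loops Classified loop table (from [classify_loops()]).
#' @param bins A [bin_table()].
#' @inheritParams gene_bait_bins
#' @return `genes` with an `enhancer_class` column appended.
#' @export
assign_enhancer_class <- function(genes, peaks, loops, bins,
                                  promoter_pad = 2000) {
  assert_cols(peaks, c("chrom", "start", "end", "best_n", "repeat_class"),
              "annotated peaks")
  bins <- bin_table(bins)
  genes <- as_tibble(genes)
  if (!all(c("promoter_start", "promoter_end") %in% names(genes))) {
    assert_cols(genes, c("gene_id", "chrom", "tss"), "genes")
    genes <- genes |>
      mutate(promoter_start = pmax(0, .data$tss - promoter_pad),
             promoter_end = .data$tss + promoter_pad)
  }
  ggaa_peaks <- as_tibble(peaks) |> filter(.data$best_n >= 1)

  # class P: GGAA-bearing peak overlapping the promoter
  prom <- genes |>
    transmute(.data$gene_id, .data$chrom,
              start = .data$promoter_start, end = .data$promoter_end)
  p_genes <- character(0)
  if (nrow(ggaa_peaks) > 0) {
    ov <- overlap_pairs(prom, ggaa_peaks)
    p_genes <- unique(prom$gene_id[ov$query_idx])
  }

  # peak-bearing bins by repeat class
  bin_class <- peak_bins_by_class(ggaa_peaks, bins)

  gl <- gene_loops(genes, loops, bins, promoter_pad)
  linked <- gl |>
    left_join(bin_class, by = c(oe_bin = "bin_id")) |>
    group_by(.data$gene_id) |>
    summarise(any_long = any(coalesce(.data$has_long, FALSE)),
              any_short = any(coalesce(.data$has_short, FALSE)),
              .groups = "drop")

  genes |>
    left_join(linked, by = "gene_id") |>
    mutate(
      enhancer_class = case_when(
        .data$gene_id %in% p_genes ~ "P",
        coalesce(.data$any_long, FALSE) ~ "distal_long",
        coalesce(.data$any_short, FALSE) ~ "distal_short",
        TRUE ~ "none"
      )
    ) |>
    select(-"any_long", -"any_short")
}

# bins holding at least one long / short repeat peak
peak_bins_by_class <- function(ggaa_peaks, bins) {
  if (nrow(ggaa_peaks) == 0) {
    return(tibble(bin_id = integer(), has_long = logical(), has_short = logical()))
  }
  ov <- overlap_pairs(ggaa_peaks, bins)
  ov |>
    transmute(bin_id = bins$bin_id[.data$subject_idx],
              repeat_class = ggaa_peaks$repeat_class[.data$query_idx]) |>
    group_by(.data$bin_id) |>
    summarise(has_long = any(.data$repeat_class == "long"),
              has_short = any(.data$repeat_class == "short"),
              .groups = "drop")
}

#' Summarize per-gene contact changes
#'
#' Reduces a gene's relevant loops to one label: `lost`/`gained` when every
#' loop is lost/gained; otherwise `up`/`down` when the mean differential
#' strength exceeds a dead-band `deadband` in either direction; `common`
#' within the dead-band. Genes appear only if they have at least one loop.
#'
#' @param gene_loop_table Data frame with `gene_id`, `label` and
#'   `delta_log2` (e.g. [gene_loops()] joined with
#'   [loop_strength_change()]).
#' @param deadband Half-width of the "no change" band on the log2 scale.
#' @return Tibble (`gene_id`, `n_loops`, `mean_delta`, `contact_change`).
#' @export
contact_change_summary <- function(gene_loop_table, deadband = 0.25) {
  assert_cols(gene_loop_table, c("gene_id", "label", "delta_log2"),
              "gene loop table")
  if (nrow(gene_loop_table) == 0) {
    abort("no gene has a relevant loop")
  }
  gene_loop_table |>
    group_by(.data$gene_id) |>
    summarise(
      n_loops = n(),
      mean_delta = mean(.data$delta_log2),
      all_lost = all(.data$label == "lost"),
      all_gained = all(.data$label == "gained"),
      .groups = "drop"
    ) |>
    mutate(
      contact_change = case_when(
        .data$all_lost ~ "lost",
        .data$all_gained ~ "gained",
        .data$mean_delta > deadband ~ "up",
        .data$mean_delta < -deadband ~ "down",
        TRUE ~ "common"
      )
    ) |>
    select(-"all_lost", -"all_gained")
}

#' Genes with cohesin/CTCF-anchored promoter loops
#'
#' Selects genes that are *not* EWS::FLI1 direct targets and have at least
#' one promoter loop anchored by cohesin at both anchor bins and by CTCF at
#' at least one of them -- the CTCF/cohesin loop gene set examined for
#' EWS::FLI1-independent regulation.
#'
#' @param genes Gene annotation.
#' @param loops Classified loop table.
#' @param bins A [bin_table()].
#' @param cohesin_peaks,ctcf_peaks Peak interval tables (`chrom`, `start`,
#'   `end`).
#' @param direct_targets Character vector of gene ids to exclude.
#' @inheritParams gene_bait_bins
#' @return Tibble of selected genes (subset of `genes`).
#' @export
select_ctcf_cohesin_genes <- function(genes, loops, bins, cohesin_peaks,
                                      ctcf_peaks, direct_targets = character(0),
                                      promoter_pad = 2000) {
  bins <- bin_table(bins)
  coh_bins <- bins_with_peak(cohesin_peaks, bins)
  ctcf_bins <- bins_with_peak(ctcf_peaks, bins)
  gl <- gene_loops(genes, loops, bins, promoter_pad)
  keep <- gl |>
    mutate(
      coh_both = .data$bait_bin %in% coh_bins & .data$oe_bin %in% coh_bins,
      ctcf_any = .data$bait_bin %in% ctcf_bins | .data$oe_bin %in% ctcf_bins
    ) |>
    filter(.data$coh_both, .data$ctcf_any) |>
    distinct(.data$gene_id)
  as_tibble(genes) |>
    filter(.data$gene_id %in% keep$gene_id,
           !.data$gene_id %in% direct_targets)
}

bins_with_peak <- function(peaks, bins) {
  if (is.null(peaks) || nrow(peaks) == 0) return(integer(0))
  ov <- overlap_pairs(as_tibble(peaks), bins)
  unique(bins$bin_id[ov$subject_idx])
}

#' Compare expression changes across gene classes
#'
#' Computes per-group medians and quartiles of an expression change column
#' and the rank-based group test used for such boxplots: Mann-Whitney
#' (Wilcoxon rank-sum) for two groups, Kruskal-Wallis for more.
#'
#' @param data Data frame of genes with a class column and a value column.
#' @param class Grouping column (tidy-eval).
#' @param value Value column (tidy-eval), e.g. `log2fc`.
#' @return Object of class `class_expression` with `summary` (per-group
#'   n/median/quartiles) and `test` (method, statistic, p_value) tibbles;
#'   `tidy()` returns the summary, `glance()` the test.
#' @export
expression_by_class <- function(data, class, value) {
  class_quo <- enquo(class)
  value_quo <- enquo(value)
  dat <- as_tibble(data) |>
    transmute(class = as.character(!!class_quo), value = !!value_quo) |>
    filter(!is.na(.data$class), !is.na(.data$value))
  k <- length(unique(dat$class))
  if (k < 2) abort("need at least two non-empty groups to compare")
  summary <- dat |>
    group_by(.data$class) |>
    summarise(n = n(), median = median(.data$value),
              q25 = quantile(.data$value, 0.25),
              q75 = quantile(.data$value, 0.75), .groups = "drop")
  if (k == 2) {
    ht <- wilcox.test(value ~ class, data = dat, exact = FALSE)
    method <- "Mann-Whitney"
  } else {
    ht <- kruskal.test(value ~ class, data = dat)
    method <- "Kruskal-Wallis"
  }
  structure(
    list(summary = summary,
         test = tibble(method = method,
                       statistic = unname(ht$statistic),
                       p_value = ht$p.value)),
    class = "class_expression"
  )
}

#' @export
print.class_expression <- function(x, ...) {
  print(x$summary)
  cat(sprintf("%s test: statistic = %.4g, p = %.3g\n",
              x$test$method, x$test$statistic, x$test$p_value))
  invisible(x)
}

#' @export
tidy.class_expression <- function(x, ...) x$summary

#' @export
glance.class_expression <- function(x, ...) x$test
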
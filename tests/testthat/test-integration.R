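# shared fixture: the miniature study with planted gene classes
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(seed = 3)
    cache
  }
})

classified_loops <- function(st) {
  classify_loops(filter_loop_calls(st$calls), st$bins)
}

test_that("direct-target selection is strict on the fold-change bound", {
  deg <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        log2fc = c(0.5, -0.5, 0.51, -0.7))
  expect_equal(select_direct_targets(deg)$gene_id, c("c", "d"))
  expect_equal(nrow(select_direct_targets(deg[0, ])), 0)
})

test_that("planted enhancer classes are recovered with correct precedence", {
  st <- study_fixture()
  ann <- annotate_peaks(st$peaks, st$genome)
  loops <- classified_loops(st)
  out <- assign_enhancer_class(st$genes, ann, loops, st$bins)
  expect_equal(out$enhancer_class, st$truth$gene_class$enhancer_class)

  # precedence: a gene looped to both long and short repeat bins is distal_long
  genes2 <- st$genes[st$genes$gene_id == "g_short_common", ]
  extra_loop <- tibble::tibble(
    bait_bin = 130L, oe_bin = 180L, label = "common"
  )
  loops2 <- dplyr::bind_rows(loops |> dplyr::select(bait_bin, oe_bin, label),
                             extra_loop)
  out2 <- assign_enhancer_class(genes2, ann, loops2, st$bins)
  expect_equal(out2$enhancer_class, "distal_long")

  # no peaks anywhere -> none
  out3 <- assign_enhancer_class(st$genes, ann[ann$best_n < 0, ], loops, st$bins)
  expect_true(all(out3$enhancer_class == "none"))
})

test_that("per-gene contact change follows the all-lost/all-gained/dead-band rule", {
  gl <- tibble::tibble(
    gene_id = c("a", "a", "b", "c", "c", "d", "e"),
    label = c("lost", "lost", "gained", "lost", "common", "common", "common"),
    delta_log2 = c(-2, -1.5, 2, -1.5, -0.4, 0.1, 0.3)
  )
  out <- contact_change_summary(gl, deadband = 0.25)
  expect_equal(out$contact_change[match(c("a", "b", "c", "d", "e"),
                                        out$gene_id)],
               c("lost", "gained", "down", "common", "up"))
  expect_error(contact_change_summary(gl[0, ]), "no gene")
})

test_that("planted contact-change labels are recovered through O/E strengths", {
  st <- study_fixture()
  loops <- classified_loops(st)
  oe_wt <- decay_normalize(row_normalize(st$maps$WT))
  oe_ko <- decay_normalize(row_normalize(st$maps$KO))
  deltas <- loop_strength_change(oe_wt, oe_ko, loops)
  gl <- gene_loops(st$genes, deltas, st$bins)
  out <- contact_change_summary(gl)
  want <- st$truth$contact_change
  expect_equal(out$contact_change[match(want$gene_id, out$gene_id)],
               want$contact_change)
})

test_that("cohesin/CTCF anchored gene selection matches a brute-force oracle", {
  withr::with_seed(13, {
    st <- study_fixture()
    bins <- st$bins
    # random cohesin/CTCF peak tracks over bins
    peak_track <- function(n) {
      ids <- sample(nrow(bins), n)
      tibble::tibble(chrom = bins$chrom[ids], start = bins$start[ids] + 100L,
                     end = bins$start[ids] + 200L)
    }
    cohesin <- peak_track(120)
    ctcf <- peak_track(60)
    loops <- tibble::tibble(
      bait_bin = sample(c(110L, 120L, 130L, 140L, 150L), 30, replace = TRUE),
      oe_bin = sample(155:250, 30, replace = TRUE),
      label = "common"
    )
    got <- select_ctcf_cohesin_genes(st$genes, loops, bins, cohesin, ctcf,
                                     direct_targets = "g_P")
    # oracle: explicit loops over genes and anchors
    in_track <- function(track) {
      hits <- rep(FALSE, nrow(bins))
      for (i in seq_len(nrow(track))) {
        j <- which(bins$chrom == track$chrom[i] &
                     bins$start < track$end[i] & bins$end > track$start[i])
        hits[j] <- TRUE
      }
      which(hits)
    }
    coh_bins <- in_track(cohesin)
    ctcf_bins <- in_track(ctcf)
    want <- character(0)
    for (g in st$genes$gene_id) {
      tss <- st$genes$tss[st$genes$gene_id == g]
      pbins <- which(bins$start < tss + 2000 & bins$end > tss - 2000)
      for (k in seq_len(nrow(loops))) {
        if (loops$bait_bin[k] %in% pbins &&
            loops$bait_bin[k] %in% coh_bins && loops$oe_bin[k] %in% coh_bins &&
            (loops$bait_bin[k] %in% ctcf_bins || loops$oe_bin[k] %in% ctcf_bins) &&
            g != "g_P") {
          want <- union(want, g)
        }
      }
    }
    expect_setequal(got$gene_id, want)
  })
})

test_that("group expression summaries use the right rank test", {
  withr::with_seed(5, {
    dat <- tibble::tibble(
      cls = rep(c("P", "distal_long", "distal_short"), each = 100),
      log2fc = c(rnorm(100, 0), rnorm(100, -1), rnorm(100, 0))
    )
    res <- expression_by_class(dat, cls, log2fc)
    expect_equal(res$test$method, "Kruskal-Wallis")
    expect_lt(res$test$p_value, 1e-6)
    med <- tidy(res)
    expect_lt(med$median[med$class == "distal_long"],
              min(med$median[med$class != "distal_long"]))

    # two groups -> Mann-Whitney, and near-null p on identical distributions
    two <- dat[dat$cls != "distal_long", ]
    res2 <- expression_by_class(two, cls, log2fc)
    expect_equal(res2$test$method, "Mann-Whitney")
    expect_gt(res2$test$p_value, 0.05)
    # k = 2 Kruskal-Wallis agrees with Mann-Whitney qualitatively
    kw <- stats::kruskal.test(log2fc ~ cls, data = two)
    expect_equal(res2$test$p_value < 0.05, kw$p.value < 0.05)

    expect_error(expression_by_class(dat[dat$cls == "P", ], cls, log2fc),
                 "two")
  })
})
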
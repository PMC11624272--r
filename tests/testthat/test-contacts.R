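test_that("row normalization makes positive rows sum to one", {
  withr::with_seed(3, {
    for (i in 1:5) {
      m <- random_contact_matrix(n_bins = 60)
      r <- row_normalize(m)
      sums <- tapply(r$pixels$value, r$pixels$row_id, sum)
      expect_lt(max(abs(sums - 1)), 1e-12)
      # single-pixel rows carry the full mass
      single <- names(which(table(r$pixels$row_id) == 1))
      if (length(single) > 0) {
        expect_equal(r$pixels$value[r$pixels$row_id %in% as.integer(single)],
                     rep(1, length(single)))
      }
    }
  })
  expect_error(row_normalize(row_normalize(random_contact_matrix())), "raw")
})

test_that("sparse normalizations match the dense oracle", {
  withr::with_seed(9, {
    for (i in 1:8) {
      m <- random_contact_matrix(n_bins = sample(20:200, 1))
      R <- dense_row_normalize(dense_from_raw(m))
      r <- row_normalize(m)
      for (k in seq_len(nrow(r$pixels))) {
        expect_equal(r$pixels$value[k],
                     R[r$pixels$row_id[k], r$pixels$col_id[k]])
      }
      OE <- dense_decay_normalize(R, m$bins$is_bait)
      oe <- decay_normalize(r)
      expect_true(all(m$bins$is_bait[oe$pixels$row_id]))
      got <- oe$pixels$value
      want <- OE[cbind(oe$pixels$row_id, oe$pixels$col_id)]
      expect_equal(got, want)
    }
  })
})

test_that("O/E of a noiseless power-law matrix is flat at 1", {
  bins <- simulate_bins(c(simchr1 = 600e3), bait_bins = c(60L, 90L, 120L, 150L))
  m <- simulate_contact_maps(bins, conditions = "X", decay_exp = 1.2,
                             max_range = 150e3, noise = "none", seed = 1)$X
  oe <- decay_normalize(row_normalize(m))
  expect_lt(max(abs(oe$pixels$value - 1)), 1e-9)
})

test_that("normalization commutes with global scaling of the raw matrix", {
  withr::with_seed(21, {
    m <- random_contact_matrix(n_bins = 80)
    m7 <- m
    m7$pixels$count <- m7$pixels$count * 7
    oe1 <- decay_normalize(row_normalize(m))
    oe7 <- decay_normalize(row_normalize(m7))
    expect_equal(oe1$pixels, oe7$pixels)
  })
})

test_that("decay normalization needs bait rows and a row-normalized input", {
  m <- random_contact_matrix(n_bins = 30, n_bait = 0)
  expect_error(decay_normalize(row_normalize(m)), "bait")
  expect_error(decay_normalize(random_contact_matrix()), "row-normalized")
})

test_that("downsampling equalizes on-target totals exactly without growing support", {
  bins <- simulate_bins(c(simchr1 = 300e3), bait_bins = c(30L, 60L))
  mk <- function(base, seed, cond) {
    simulate_contact_maps(bins, conditions = cond, base = base,
                          max_range = 60e3, noise = "poisson", seed = seed)[[cond]]
  }
  m1 <- mk(40, 1, "A"); m2 <- mk(90, 2, "B"); m3 <- mk(140, 3, "C")
  ds <- downsample_to_match(list(m1, m2, m3), seed = 5)
  target <- min(sapply(list(m1, m2, m3), on_target_total))
  expect_equal(sapply(ds, on_target_total), rep(target, 3))
  for (k in 1:3) {
    before <- list(m1, m2, m3)[[k]]$pixels
    after <- ds[[k]]$pixels
    j <- dplyr::left_join(after, before, by = c("bin1_id", "bin2_id"),
                          suffix = c("_after", "_before"))
    expect_true(all(!is.na(j$count_before)))          # support never grows
    expect_true(all(j$count_after <= j$count_before)) # counts never grow
  }
  # identical matrices pass through unchanged
  same <- downsample_to_match(list(m1, m1), seed = 9)
  expect_equal(same[[1]]$pixels, m1$pixels)
  # determinism per seed
  ds2 <- downsample_to_match(list(m1, m2, m3), seed = 5)
  expect_equal(lapply(ds, function(m) m$pixels), lapply(ds2, function(m) m$pixels))

  # an empty matrix drags every on-target total to zero
  empty <- contact_matrix(bins, tibble::tibble(bin1_id = integer(),
                                               bin2_id = integer(),
                                               count = numeric()))
  ds0 <- downsample_to_match(list(m1, empty), seed = 1)
  expect_equal(sapply(ds0, on_target_total), c(0, 0))

  other <- simulate_bins(c(simchr1 = 300e3), bait_bins = c(10L, 20L))
  m_other <- simulate_contact_maps(other, conditions = "A", max_range = 60e3,
                                   seed = 1)$A
  expect_error(downsample_to_match(list(m1, m_other)), "different bin tables")
})

test_that("loop strength reads O/E pixels and differential strength has the right sign", {
  bins <- simulate_bins(c(simchr1 = 900e3), bait_bins = c(110L, 120L, 130L,
                                                          140L, 150L))
  loops <- tibble::tibble(bait_bin = c(120L, 130L, 140L),
                          oe_bin = c(160L, 165L, 180L), fold = 4,
                          in_WT = c(TRUE, TRUE, FALSE),
                          in_KO = c(FALSE, TRUE, TRUE))
  maps <- simulate_contact_maps(bins, loops, max_range = 300e3,
                                noise = "none", seed = 1)
  oe_wt <- decay_normalize(row_normalize(maps$WT))
  oe_ko <- decay_normalize(row_normalize(maps$KO))

  d <- loop_strength_change(oe_wt, oe_ko, loops)
  expect_equal(d$delta_log2[2], 0, tolerance = 0.02)  # common loop
  expect_lt(d$delta_log2[1], -1)                      # lost loop
  expect_gt(d$delta_log2[3], 1)                       # gained loop
  # absent pixel reads 0
  s <- loop_strength(oe_wt, tibble::tibble(bait_bin = 110L, oe_bin = 250L))
  expect_equal(s$strength, 0)
  expect_error(loop_strength(oe_wt, tibble::tibble(bait_bin = 1L, oe_bin = 9999L)),
               "anchor")
  # window averaging dilutes the focal pixel with its (mostly absent)
  # neighborhood but keeps its contribution
  sw <- loop_strength(oe_wt, loops[2, ], window = 1L)
  s0 <- loop_strength(oe_wt, loops[2, ], window = 0L)
  expect_lt(sw$strength, s0$strength)
  expect_gt(sw$strength, s0$strength / 9)
})
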
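test_that("generators are byte-identical per seed", {
  s1 <- simulate_genome(run_spec = tibble::tibble(n_motifs = 3, gap = 2),
                        seed = 12)
  s2 <- simulate_genome(run_spec = tibble::tibble(n_motifs = 3, gap = 2),
                        seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(
    s1$genome,
    simulate_genome(run_spec = tibble::tibble(n_motifs = 3, gap = 2),
                    seed = 13)$genome
  ))
  c1 <- simulate_cohort(n_patients = 20, n_genes = 60,
                        signature = simulate_signature(10), seed = 3)
  c2 <- simulate_cohort(n_patients = 20, n_genes = 60,
                        signature = simulate_signature(10), seed = 3)
  expect_identical(c1, c2)
})

test_that("planted run spans follow the placement arithmetic", {
  sim <- simulate_genome(run_spec = tibble::tibble(n_motifs = c(5, 2, 1),
                                                   gap = c(0, 5, 0)),
                         seed = 1)
  spans <- sim$runs$end - sim$runs$start
  expect_setequal(spans, c(20, 13, 4))  # 4n + gap(n-1)
  # empty spec -> no scanner hits anywhere
  empty <- simulate_genome(run_spec = tibble::tibble(n_motifs = integer(),
                                                     gap = integer()),
                           seed = 1)
  expect_equal(nrow(scan_genome_runs(empty$genome)), 0)
  # a run too large for its slot fails naming the offender
  expect_error(
    simulate_genome(chrom_len = 1000,
                    run_spec = tibble::tibble(n_motifs = 300, gap = 0)),
    "cannot place run"
  )
})

test_that("the scrubbed background contains only planted motifs", {
  sim <- simulate_genome(n_chrom = 2, chrom_len = 20000,
                         run_spec = tibble::tibble(n_motifs = c(6, 2),
                                                   gap = c(1, 5),
                                                   strand = c("+", "-")),
                         seed = 9)
  runs <- scan_genome_runs(sim$genome)
  expect_equal(nrow(runs), 2)
  expect_equal(as.data.frame(runs),
               as.data.frame(sim$runs[names(runs)]))
})

test_that("contact generator reproduces its power-law decay closed form", {
  bins <- simulate_bins(c(simchr1 = 600e3), bait_bins = c(60L, 100L, 140L))
  for (alpha in c(0.8, 1.5)) {
    m <- simulate_contact_maps(bins, conditions = "X", decay_exp = alpha,
                               max_range = 150e3, noise = "none", seed = 1)$X
    td <- tidy(m)
    d <- td$bin2_id - td$bin1_id
    mean_at <- function(k) mean(td$count[d == k])
    expect_equal(mean_at(20) / mean_at(10), 2^(-alpha))
    expect_equal(mean_at(40) / mean_at(20), 2^(-alpha))
  }
  expect_error(
    simulate_contact_maps(bins,
                          loops = tibble::tibble(bait_bin = 1e5, oe_bin = 2,
                                                 fold = 2, in_X = TRUE),
                          conditions = "X"),
    "outside the bin table"
  )
  expect_error(
    simulate_contact_maps(bins,
                          loops = tibble::tibble(bait_bin = 60L, oe_bin = 61L,
                                                 fold = 0.5, in_X = TRUE),
                          conditions = "X"),
    "fold"
  )
})

test_that("planted loop pixels carry the exact fold in raw O/E terms", {
  bins <- simulate_bins(c(simchr1 = 600e3), bait_bins = c(60L, 100L, 140L))
  loops <- tibble::tibble(bait_bin = 100L, oe_bin = 120L, fold = 4,
                          in_X = TRUE)
  m <- simulate_contact_maps(bins, loops, conditions = "X", decay_exp = 1,
                             base = 100, max_range = 150e3, noise = "none",
                             seed = 1)$X
  td <- tidy(m)
  planted <- td$count[td$bin1_id == 100 & td$bin2_id == 120]
  background <- td$count[td$bin1_id == 60 & td$bin2_id == 80]  # same distance
  expect_equal(planted / background, 4)
})

test_that("loop call emission follows the detection probability", {
  bins <- simulate_bins(c(simchr1 = 3e6), bin_size = 3000,
                        bait_bins = as.integer(seq(100, 900, by = 2)))
  loops <- tibble::tibble(
    bait_bin = as.integer(seq(100, 900, by = 2))[1:250],
    oe_bin = as.integer(seq(100, 900, by = 2))[1:250] + 31L,
    fold = 2, in_WT = TRUE, in_KO = TRUE
  )
  lc <- simulate_loop_calls(loops, bins, detect_prob = 0.9, seed = 6)
  n_emitted <- nrow(lc$calls)
  n_possible <- 4 * nrow(loops)
  phat <- n_emitted / n_possible
  ci <- 0.9 + c(-1, 1) * 3 * sqrt(0.9 * 0.1 / n_possible)
  expect_gt(phat, ci[1])
  expect_lt(phat, ci[2])
  # detect_prob = 0 -> empty, detect_prob = 1 -> everything
  expect_equal(nrow(simulate_loop_calls(loops, bins, detect_prob = 0,
                                        seed = 1)$calls), 0)
  expect_equal(nrow(simulate_loop_calls(loops, bins, detect_prob = 1,
                                        seed = 1)$calls), n_possible)
})

test_that("cohort generator recovers its planted hazard ratio", {
  loghrs <- vapply(1:60, function(s) {
    co <- simulate_cohort(n_patients = 200, n_genes = 40,
                          signature = simulate_signature(10), hr = 3,
                          censor_rate = 0.2, seed = s)
    fit <- survival::coxph(
      survival::Surv(co$survival$time_days, co$survival$event) ~
        co$labels$group == "signature-like"
    )
    unname(stats::coef(fit))
  }, numeric(1))
  expect_lt(abs(mean(loghrs) / log(3) - 1), 0.1)
  # censoring fraction lands near its target
  co <- simulate_cohort(n_patients = 2000, n_genes = 25,
                        signature = simulate_signature(5), hr = 1,
                        censor_rate = 0.3, seed = 1)
  expect_lt(abs(mean(1 - co$survival$event) - 0.3), 0.05)
  expect_error(simulate_cohort(n_genes = 10,
                               signature = simulate_signature(50)),
               "smaller than the signature")
  expect_error(simulate_cohort(hr = 0), "hr")
  expect_error(simulate_cohort(censor_rate = 1), "censor_rate")
})
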
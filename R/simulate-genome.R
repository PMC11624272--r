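#' Simulate a genome with planted GGAA microsatellite runs
#'
#' Generates i.i.d. background sequence at a chosen GC content, scrubs every
#' GGAA/TTCC occurrence from it (so the only motifs anywhere are the planted
#' ones and the planted motif count is unambiguous), then splices in the
#' requested runs at deterministic, evenly spaced positions. A run of
#' `n_motifs` motifs with internal gap `gap` spans
#' `4 * n_motifs + gap * (n_motifs - 1)` bp; gaps are filled with T (which
#' can create neither GGAA nor TTCC at the junctions).
#'
#' @param n_chrom Number of chromosomes (`simchr1`, ...).
#' @param chrom_len Chromosome length in bp (same for all).
#' @param run_spec Data frame with `n_motifs` (>= 1), `gap` (>= 0) and
#'   optional `strand` (`"+"` plants GGAA, `"-"` plants TTCC); one row per
#'   run. Runs are distributed round-robin across chromosomes, unless
#'   explicit `chrom` and `start` columns pin them to exact positions.
#' @param bg_gc Background GC fraction.
#' @param margin Minimum distance (bp) between a run and a chromosome end
#'   or a neighboring run's slot.
#' @param seed Integer seed; output is byte-identical per seed.
#' @return List with `genome` (named character vector) and `runs` (truth
#'   tibble: `chrom`, `start`, `end` 0-based half-open, `n_motifs`, `gap`,
#'   `strand`).
#' @examples
#' sim <- simulate_genome(run_spec = tibble::tibble(n_motifs = 5, gap = 0))
#' sim$runs
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_len = 50000L,
                            run_spec = tibble(n_motifs = integer(),
                                              gap = integer()),
                            bg_gc = 0.41, margin = 200L, seed = 1L) {
  run_spec <- as_tibble(run_spec)
  if (nrow(run_spec) > 0) {
    assert_cols(run_spec, c("n_motifs", "gap"), "run_spec")
    if (any(run_spec$n_motifs < 1)) abort("n_motifs must be >= 1")
    if (any(run_spec$gap < 0)) abort("gap must be >= 0")
  }
  if (!"strand" %in% names(run_spec)) run_spec$strand <- rep("+", nrow(run_spec))

  withr::with_seed(as.integer(seed), {
    chroms <- paste0("simchr", seq_len(n_chrom))
    genome <- vapply(chroms, function(ch) {
      scrub_motifs(random_sequence(chrom_len, bg_gc))
    }, character(1))

    truth <- tibble(chrom = character(), start = integer(), end = integer(),
                    n_motifs = integer(), gap = integer(), strand = character())
    if (nrow(run_spec) > 0) {
      if (!"chrom" %in% names(run_spec)) {
        run_spec$chrom <- chroms[((seq_len(nrow(run_spec)) - 1L) %% n_chrom) + 1L]
      }
      if (!all(run_spec$chrom %in% chroms)) abort("run_spec chrom outside genome")
      run_spec$span <- 4L * run_spec$n_motifs +
        run_spec$gap * (run_spec$n_motifs - 1L)
      placed <- if ("start" %in% names(run_spec)) {
        ok_bounds <- run_spec$start >= 0 &
          run_spec$start + run_spec$span <= chrom_len
        if (!all(ok_bounds)) {
          bad <- which(!ok_bounds)[1]
          abort(sprintf("cannot place run with n_motifs=%d at %s:%d: outside chromosome",
                        run_spec$n_motifs[bad], run_spec$chrom[bad],
                        run_spec$start[bad]))
        }
        chk <- run_spec |> mutate(end = .data$start + .data$span) |>
          arrange(.data$chrom, .data$start)
        ovl <- chk |> group_by(.data$chrom) |>
          filter(.data$start < lag(.data$end, default = -1L)) |> ungroup()
        if (nrow(ovl) > 0) abort("explicitly placed runs overlap")
        run_spec |> mutate(start = as.integer(.data$start),
                           end = .data$start + .data$span)
      } else {
        run_spec |>
        group_by(.data$chrom) |>
        group_modify(function(df, key) {
          k <- nrow(df)
          slot <- (chrom_len - 2 * margin) / k
          if (any(df$span + 2 * margin > slot)) {
            bad <- which(df$span + 2 * margin > slot)[1]
            abort(sprintf(
              "cannot place run with n_motifs=%d, gap=%d (span %d bp) on %s: slot of %.0f bp too small",
              df$n_motifs[bad], df$gap[bad], df$span[bad], key$chrom, slot))
          }
          df$start <- as.integer(margin + (seq_len(k) - 1) * slot +
                                   floor((slot - df$span) / 2))
          df$end <- df$start + df$span
          df
        }) |>
        ungroup()
      }
      for (i in seq_len(nrow(placed))) {
        motif <- if (placed$strand[i] == "-") "TTCC" else "GGAA"
        run_seq <- paste(rep(motif, placed$n_motifs[i]),
                         collapse = strrep("T", placed$gap[i]))
        ch <- placed$chrom[i]
        str_sub(genome[ch], placed$start[i] + 1, placed$end[i]) <- run_seq
      }
      truth <- placed |>
        select("chrom", "start", "end", "n_motifs", "gap", "strand") |>
        arrange(.data$chrom, .data$start)
    }
    list(genome = genome, runs = truth)
  })
}

random_sequence <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Destroy every GGAA/TTCC occurrence by mutating its last base; iterate to a
# fixed point since an edit can in principle uncover a new occurrence.
scrub_motifs <- function(seq_chr) {
  repeat {
    hits <- str_locate_all(seq_chr, "GGAA|TTCC")[[1]]
    if (nrow(hits) == 0) return(seq_chr)
    for (i in seq_len(nrow(hits))) {
      pos <- hits[i, 1]
      motif <- str_sub(seq_chr, pos, pos + 3)
      repl <- if (motif == "GGAA") "C" else "A"
      str_sub(seq_chr, pos + 3, pos + 3) <- repl
    }
  }
}

#' Simulate peaks over planted runs plus motif-free background peaks
#'
#' Emits one peak spanning each planted run (so its true best motif count is
#' the run's `n_motifs`) and `n_background` peaks centered in run-free
#' positions (true count 0), each with a -log10 q value drawn uniformly from
#' `q_range`.
#'
#' @param sim Output of [simulate_genome()].
#' @param flank Bp added on each side of a run to form its peak.
#' @param n_background Number of motif-free decoy peaks per chromosome.
#' @param width_background Width of background peaks.
#' @param q_range Range of -log10 q values.
#' @param seed Integer seed.
#' @return Peak tibble with truth columns `true_best_n`, `true_class`.
#' @export
simulate_peaks <- function(sim, flank = 150L, n_background = 10L,
                           width_background = 300L, q_range = c(10, 100),
                           seed = 1L) {
  runs <- sim$runs
  lens <- nchar(sim$genome)
  withr::with_seed(as.integer(seed), {
    planted <- runs |>
      mutate(start = pmax(0L, .data$start - flank),
             end = pmin(lens[.data$chrom], .data$end + flank),
             true_best_n = .data$n_motifs) |>
      select("chrom", "start", "end", "true_best_n")
    bg <- map(names(sim$genome), function(ch) {
      # background peaks at evenly spaced positions, nudged off planted runs
      cand <- floor(seq(width_background,
                        lens[[ch]] - 2 * width_background,
                        length.out = n_background + 2))[-c(1, n_background + 2)]
      tibble(chrom = ch, start = as.integer(cand),
             end = as.integer(cand + width_background), true_best_n = 0L)
    }) |> list_rbind()
    if (nrow(runs) > 0 && nrow(bg) > 0) {
      ov <- overlap_pairs(bg, runs |> select("chrom", "start", "end"))
      if (nrow(ov) > 0) bg <- bg[-unique(ov$query_idx), ]
    }
    peaks <- bind_rows(planted, bg) |>
      arrange(.data$chrom, .data$start) |>
      mutate(
        name = sprintf("peak_%03d", row_number()),
        q = runif(n(), q_range[1], q_range[2]),
        true_class = case_when(
          .data$true_best_n > 4 ~ "long",
          .data$true_best_n >= 1 ~ "short",
          TRUE ~ "none"
        )
      ) |>
      select("chrom", "start", "end", "name", "q", "true_best_n", "true_class")
    peaks
  })
}

#' Fixture for the peak filter: planted blacklist hits and low-q peaks
#'
#' Builds a disjoint peak table with a known number of survivors of the
#' `q >= q_min` + blacklist filter: `n_keep` clean peaks (q in `[5, 50]`),
#' `n_blacklisted` peaks covered by blacklist intervals, `n_lowq` peaks with
#' q below 5, plus `n_duplicate` exact duplicates of clean peaks (which the
#' filter must collapse).
#'
#' @param n_keep,n_blacklisted,n_lowq,n_duplicate Category sizes.
#' @param seed Integer seed.
#' @return List with `peaks`, `blacklist` and `n_expected` (= `n_keep`).
#' @export
simulate_peak_filter_fixture <- function(n_keep = 60L, n_blacklisted = 30L,
                                         n_lowq = 10L, n_duplicate = 0L,
                                         seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- n_keep + n_blacklisted + n_lowq
    start <- seq_len(n) * 1000L
    cls <- sample(rep(c("keep", "bl", "lowq"),
                      c(n_keep, n_blacklisted, n_lowq)))
    peaks <- tibble(
      chrom = "simchr1", start = start, end = start + 400L,
      name = sprintf("p%03d", seq_len(n)),
      q = ifelse(cls == "lowq", runif(n, 0, 4.9), runif(n, 5, 50)),
      planted = cls
    )
    blacklist <- peaks |>
      filter(.data$planted == "bl") |>
      transmute(.data$chrom, start = .data$start - 50L, end = .data$end + 50L)
    if (n_duplicate > 0) {
      dup <- peaks |> filter(.data$planted == "keep") |> head(n_duplicate)
      peaks <- bind_rows(peaks, dup)
    }
    list(peaks = peaks, blacklist = blacklist, n_expected = n_keep)
  })
}
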
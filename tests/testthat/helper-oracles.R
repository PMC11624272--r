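# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the scanner oracle is a plain regex + explicit loop,
# the matrix oracle works on dense matrices.

# Brute-force GGAA run scanner: enumerate motif occurrences with gregexpr,
# chain them with an explicit loop.
oracle_scan <- function(seq_chr, max_gap = 5, strand_mode = "both") {
  seq_chr <- toupper(seq_chr)
  one_strand <- function(motif, strand) {
    hits <- gregexpr(motif, seq_chr, fixed = TRUE)[[1]]
    if (hits[1] == -1) {
      return(data.frame(start = integer(0), end = integer(0),
                        n_motifs = integer(0), strand = character(0)))
    }
    starts <- as.integer(hits)
    runs <- list()
    cur <- c(starts[1], starts[1])  # first and last motif start of this run
    count <- 1L
    for (s in starts[-1]) {
      if (s - (cur[2] + 4L) <= max_gap) {
        cur[2] <- s
        count <- count + 1L
      } else {
        runs[[length(runs) + 1]] <- c(cur, count)
        cur <- c(s, s)
        count <- 1L
      }
    }
    runs[[length(runs) + 1]] <- c(cur, count)
    df <- do.call(rbind, runs)
    data.frame(start = df[, 1] - 1L, end = df[, 2] + 3L, n_motifs = df[, 3],
               strand = strand)
  }
  out <- one_strand("GGAA", "+")
  if (strand_mode == "both") out <- rbind(out, one_strand("TTCC", "-"))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(len, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Dense counterpart of the sparse normalizations, on one chromosome.
dense_from_raw <- function(m) {
  n <- nrow(m$bins)
  M <- matrix(0, n, n)
  px <- m$pixels
  for (i in seq_len(nrow(px))) {
    M[px$bin1_id[i], px$bin2_id[i]] <- px$count[i]
    M[px$bin2_id[i], px$bin1_id[i]] <- px$count[i]
  }
  M
}

dense_row_normalize <- function(M) {
  rs <- rowSums(M)
  out <- M
  for (i in seq_len(nrow(M))) {
    if (rs[i] > 0) out[i, ] <- M[i, ] / rs[i]
  }
  out
}

# O/E over bait rows with zeros counted across the whole chromosome span
dense_decay_normalize <- function(R, is_bait) {
  n <- nrow(R)
  expected <- numeric(n)  # index d + 1
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in which(is_bait)) {
      js <- c(i - d, if (d > 0) i + d)
      js <- js[js >= 1 & js <= n]
      vals <- c(vals, R[i, js])
    }
    expected[d + 1] <- if (length(vals) > 0) mean(vals) else NA_real_
  }
  OE <- matrix(NA_real_, n, n)
  for (i in which(is_bait)) {
    for (j in seq_len(n)) {
      e <- expected[abs(i - j) + 1]
      if (!is.na(e) && e > 0) OE[i, j] <- R[i, j] / e
    }
  }
  OE
}

# Random raw contact matrix on one chromosome, integer counts.
random_contact_matrix <- function(n_bins = 50, density = 0.15, n_bait = 10,
                                  max_count = 20) {
  bins <- tibble::tibble(
    chrom = "chrT", start = (seq_len(n_bins) - 1) * 1000L,
    end = seq_len(n_bins) * 1000L, bin_id = seq_len(n_bins),
    is_bait = seq_len(n_bins) %in% sample(n_bins, n_bait)
  )
  all_pairs <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE))
  chosen <- sample(all_pairs, ceiling(density * length(all_pairs)))
  idx <- arrayInd(chosen, c(n_bins, n_bins))
  px <- tibble::tibble(
    bin1_id = pmin(idx[, 1], idx[, 2]), bin2_id = pmax(idx[, 1], idx[, 2]),
    count = sample.int(max_count, length(chosen), replace = TRUE)
  )
  contact_matrix(bins, px, condition = "rand")
}

# on-target total of a raw contact matrix
on_target_total <- function(m) {
  b <- m$bins$is_bait
  on <- b[m$pixels$bin1_id] | b[m$pixels$bin2_id]
  sum(m$pixels$count[on])
}

expect_no_label_errors <- function(labels, truth) {
  merged <- merge(labels, truth, by = "sample_id")
  expect_equal(sum(merged$label != merged$group), 0)
}
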
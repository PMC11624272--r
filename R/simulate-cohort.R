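#' Simulate a directed expression signature
#'
#' @param n_genes Number of signature genes.
#' @param frac_up Fraction with direction `"up"`.
#' @param prefix Gene id prefix.
#' @return Tibble (`gene_id`, `direction`).
#' @export
simulate_signature <- function(n_genes = 50L, frac_up = 0.5,
                               prefix = "sig") {
  n_up <- round(n_genes * frac_up)
  tibble(
    gene_id = sprintf("%s_%04d", prefix, seq_len(n_genes)),
    direction = rep(c("up", "down"), c(n_up, n_genes - n_up))
  )
}

#' Simulate a patient cohort with a planted survival-linked signature
#'
#' Expression: every gene gets a uniform baseline; in "signature-like"
#' patients, signature genes are shifted by `+effect` (direction up) or
#' `-effect` (down); Gaussian noise with sd `noise_sd` is added everywhere.
#' Survival: exponential event times at `baseline_rate` per day, multiplied
#' by `hr` for signature-like patients (proportional hazards by
#' construction); censoring is uniform over a follow-up horizon solved so
#' the expected censored fraction under the baseline hazard equals
#' `censor_rate`.
#'
#' @param n_patients Cohort size.
#' @param n_genes Total genes (must be >= the signature size).
#' @param signature Tibble (`gene_id`, `direction`); defaults to
#'   [simulate_signature()] with 50 genes. Signature gene ids are included
#'   among the `n_genes` genes.
#' @param effect Expression shift (log2 units) in signature-like patients.
#' @param noise_sd Gaussian noise sd.
#' @param frac_like Fraction of signature-like patients.
#' @param hr Planted hazard ratio (> 0) of signature-like vs different.
#' @param baseline_rate Baseline event rate per day.
#' @param censor_rate Expected censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List: `expression` (gene_id + one column per sample),
#'   `survival` (`sample_id`, `time_days`, `event`), `labels`
#'   (`sample_id`, `group` in signature-like/-different), `signature`.
#' @export
simulate_cohort <- function(n_patients = 200L, n_genes = 1000L,
                            signature = simulate_signature(),
                            effect = 2, noise_sd = 1, frac_like = 0.5,
                            hr = 3, baseline_rate = 0.01, censor_rate = 0.2,
                            seed = 1L) {
  assert_cols(signature, c("gene_id", "direction"), "signature")
  if (hr <= 0) abort("hr must be positive")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1)")
  n_sig <- nrow(signature)
  if (n_genes < n_sig) {
    abort(sprintf("n_genes (%d) is smaller than the signature (%d genes)",
                  n_genes, n_sig))
  }
  withr::with_seed(as.integer(seed), {
    gene_ids <- c(signature$gene_id,
                  sprintf("bg_%05d", seq_len(n_genes - n_sig)))
    sample_ids <- sprintf("pt_%03d", seq_len(n_patients))
    n_like <- round(frac_like * n_patients)
    like <- sample(c(rep(TRUE, n_like), rep(FALSE, n_patients - n_like)))

    mu <- runif(n_genes, 4, 12)
    shift <- numeric(n_genes)
    shift[seq_len(n_sig)] <- ifelse(signature$direction == "up", effect, -effect)
    m <- matrix(mu, n_genes, n_patients) +
      outer(shift, as.numeric(like)) +
      matrix(rnorm(n_genes * n_patients, sd = noise_sd), n_genes, n_patients)
    colnames(m) <- sample_ids
    expression <- bind_cols(tibble(gene_id = gene_ids), as_tibble(m))

    rate <- baseline_rate * hr^as.numeric(like)
    t_event <- rexp(n_patients, rate)
    if (censor_rate > 0) {
      # horizon F with (1 - exp(-lambda F)) / (lambda F) = censor_rate
      x <- uniroot(function(z) (1 - exp(-z)) / z - censor_rate,
                   interval = c(1e-8, 1e4), tol = 1e-10)$root
      horizon <- x / baseline_rate
      t_cens <- runif(n_patients, 0, horizon)
    } else {
      t_cens <- rep(Inf, n_patients)
    }
    survival <- tibble(
      sample_id = sample_ids,
      time_days = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
    labels <- tibble(
      sample_id = sample_ids,
      group = if_else(like, "signature-like", "signature-different")
    )
    list(expression = expression, survival = survival, labels = labels,
         signature = as_tibble(signature))
  })
}

#' Simulate a concordant/discordant pair of DEG contrasts
#'
#' Builds two differential-expression tables sharing `n_concordant` genes
#' significant in both with the same sign, `n_discordant` significant with
#' opposite signs, and `n_nonsig` genes failing the FDR cut in at least one
#' table -- the counting fixture for signature derivation.
#'
#' @param n_concordant,n_discordant,n_nonsig Category sizes.
#' @param effect Absolute log2 fold change of significant genes.
#' @param fdr_sig,fdr_nonsig FDR values assigned below/above the cut.
#' @param seed Integer seed.
#' @return List: `deg_a`, `deg_b`, `truth` (the concordant directed genes).
#' @export
simulate_deg_pair <- function(n_concordant = 50L, n_discordant = 20L,
                              n_nonsig = 30L, effect = 1.5,
                              fdr_sig = 0.001, fdr_nonsig = 0.2, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n <- n_concordant + n_discordant + n_nonsig
    ids <- sprintf("deg_%04d", seq_len(n))
    kind <- rep(c("conc", "disc", "ns"), c(n_concordant, n_discordant, n_nonsig))
    sign_a <- sample(c(-1, 1), n, replace = TRUE)
    sign_b <- ifelse(kind == "disc", -sign_a, sign_a)
    fdr_a <- ifelse(kind == "ns" & runif(n) < 0.5, fdr_nonsig, fdr_sig)
    fdr_b <- ifelse(kind == "ns" & fdr_a < fdr_nonsig, fdr_nonsig, fdr_sig)
    deg_a <- tibble(gene_id = ids, log2fc = sign_a * effect, fdr = fdr_a)
    deg_b <- tibble(gene_id = ids, log2fc = sign_b * effect, fdr = fdr_b)
    truth <- tibble(gene_id = ids[kind == "conc"],
                    direction = if_else(sign_a[kind == "conc"] > 0,
                                        "up", "down"))
    list(deg_a = deg_a, deg_b = deg_b, truth = truth)
  })
}
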
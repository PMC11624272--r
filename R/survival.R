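#' Compare survival between signature groups
#'
#' Kaplan-Meier estimates per group plus a two-group Cox proportional-
#' hazards fit, with `"signature-different"` as the reference so the hazard
#' ratio reads as the excess hazard of the signature-like (STAG2-loss-like)
#' group.
#'
#' @param labels Tibble (`sample_id`, `label`) as produced by
#'   [classify_cohort()] / `tidy()`; any two-level label column works.
#' @param survival_data Tibble (`sample_id`, `time_days`, `event`) with
#'   `event` 1 = death observed, 0 = censored.
#' @return Object of class `survival_comparison` holding the `coxph` and
#'   `survfit` fits; `glance()` gives HR, 95% CI, p, n and event counts,
#'   `tidy()` the Kaplan-Meier table.
#' @export
survival_compare <- function(labels, survival_data) {
  assert_cols(labels, c("sample_id", "label"), "labels")
  assert_cols(survival_data, c("sample_id", "time_days", "event"),
              "survival data")
  dat <- inner_join(as_tibble(labels), as_tibble(survival_data),
                    by = "sample_id")
  if (nrow(dat) == 0) abort("labels and survival data share no sample")
  if (any(dat$time_days < 0)) abort("negative survival time")
  if (!all(dat$event %in% c(0, 1))) abort("`event` must be 0/1")
  groups <- unique(dat$label)
  if (length(groups) != 2) {
    abort(sprintf("need exactly two groups, got %d", length(groups)))
  }
  if (sum(dat$event) == 0) abort("no events observed; cannot fit")
  ref <- if ("signature-different" %in% groups) "signature-different" else sort(groups)[1]
  dat$group <- stats::relevel(factor(dat$label), ref = ref)
  cox <- survival::coxph(survival::Surv(time_days, event) ~ group, data = dat)
  km <- survival::survfit(survival::Surv(time_days, event) ~ group, data = dat)
  structure(list(cox = cox, km = km, data = dat, reference = ref),
            class = "survival_comparison")
}

#' @export
glance.survival_comparison <- function(x, ...) {
  s <- summary(x$cox)
  ci <- s$conf.int
  tibble(
    hr = unname(s$coefficients[1, "exp(coef)"]),
    hr_low = unname(ci[1, "lower .95"]),
    hr_high = unname(ci[1, "upper .95"]),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    n = x$cox$n,
    n_events = x$cox$nevent,
    reference = x$reference
  )
}

#' @export
tidy.survival_comparison <- function(x, ...) {
  s <- summary(x$km)
  strata <- if (is.null(s$strata)) rep("all", length(s$time)) else as.character(s$strata)
  tibble(
    group = sub("^group=", "", strata),
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    estimate = s$surv,
    std_error = s$std.err,
    conf_low = s$lower,
    conf_high = s$upper
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<survival_comparison> HR = %.3f [%.3f, %.3f], p = %.3g (%d samples, %d events; reference: %s)\n",
    g$hr, g$hr_low, g$hr_high, g$p_value, g$n, g$n_events, g$reference
  ))
  invisible(x)
}

#' Kaplan-Meier curves for a survival comparison
#' @param object A `survival_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  km <- tidy(object)
  start <- km |> distinct(.data$group) |>
    mutate(time = 0, estimate = 1)
  bind_rows(start, km |> select("group", "time", "estimate")) |>
    ggplot(aes(x = .data$time, y = .data$estimate, color = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (days)", y = "survival probability", color = NULL) +
    theme_minimal()
}

#' Flag STAG2 wild-type samples with a mutant-like transcriptome (WT*)
#'
#' Projects the full transcriptome onto its top principal components,
#' splits the cohort with two-group k-means, and flags the wild-type (WT)
#' samples falling in the cluster holding the majority of mutant (MUT)
#' samples -- an algorithmic reading of the "WT*" cases whose expression
#' clusters with STAG2 mutants. A tie in the mutant split yields no flags
#' and a warning.
#'
#' @param expr Expression table (`gene_id` + sample columns).
#' @param mutation_status Tibble (`sample_id`, `status`) with status
#'   `"WT"`/`"MUT"`; both must be present.
#' @param n_pcs Number of principal components to cluster on.
#' @param seed Integer seed for the k-means restarts.
#' @return `mutation_status` with a logical `wt_star` column.
#' @export
flag_wtstar <- function(expr, mutation_status, n_pcs = 2L, seed = 1L) {
  assert_cols(mutation_status, c("sample_id", "status"), "mutation status")
  if (!all(c("WT", "MUT") %in% mutation_status$status)) {
    abort("both WT and MUT samples are required")
  }
  pca <- pca_project(expr, n_components = n_pcs)
  scores <- pca$scores |> inner_join(as_tibble(mutation_status), by = "sample_id")
  x <- as.matrix(scores[paste0("PC", seq_len(n_pcs))])
  cl <- withr::with_seed(as.integer(seed),
                         stats::kmeans(x, centers = 2, nstart = 10))
  mut_counts <- table(factor(cl$cluster[scores$status == "MUT"], levels = 1:2))
  out <- as_tibble(mutation_status)
  if (mut_counts[1] == mut_counts[2]) {
    warn("MUT samples split evenly between clusters; flagging no WT* cases")
    return(out |> mutate(wt_star = FALSE))
  }
  mut_cluster <- as.integer(names(which.max(mut_counts)))
  flagged <- scores$sample_id[cl$cluster == mut_cluster & scores$status == "WT"]
  out |> mutate(wt_star = .data$status == "WT" & .data$sample_id %in% flagged)
}
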
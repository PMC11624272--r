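#' Intersect two differential-expression contrasts into a directed signature
#'
#' A gene enters the signature when it is significant (FDR strictly below
#' `fdr_max`) in both contrasts -- typically a patient contrast (STAG2
#' mutant vs wild type) and a cell-line contrast (STAG2 KO vs WT) -- with
#' the same log2 fold-change sign. That shared sign becomes the gene's
#' direction.
#'
#' @param deg_a,deg_b Data frames with `gene_id`, `log2fc`, `fdr`.
#' @param fdr_max Exclusive FDR threshold.
#' @return Tibble (`gene_id`, `direction`, `log2fc_a`, `log2fc_b`).
#' @export
intersect_degs <- function(deg_a, deg_b, fdr_max = 0.05) {
  for (d in list(deg_a, deg_b)) {
    assert_cols(d, c("gene_id", "log2fc", "fdr"), "contrast table")
  }
  inner_join(as_tibble(deg_a), as_tibble(deg_b), by = "gene_id",
             suffix = c("_a", "_b")) |>
    filter(.data$fdr_a < fdr_max, .data$fdr_b < fdr_max,
           .data$log2fc_a != 0,
           sign(.data$log2fc_a) == sign(.data$log2fc_b)) |>
    transmute(.data$gene_id,
              direction = if_else(.data$log2fc_a > 0, "up", "down"),
              .data$log2fc_a, .data$log2fc_b)
}

# expression tibble (gene_id + one column per sample) -> genes x samples matrix
expr_matrix <- function(expr) {
  assert_cols(expr, "gene_id", "expression table")
  if (anyDuplicated(expr$gene_id)) abort("duplicated gene_id in expression table")
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  if (ncol(m) == 0) m <- matrix(numeric(0), nrow = nrow(expr), ncol = 0)
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- expr$gene_id
  m
}

#' Build extreme-phenotype centroid models for a signature
#'
#' The "KO model" takes, for each upregulated signature gene, the maximum
#' value that gene reaches anywhere in the cohort, and the minimum for each
#' downregulated gene; the "WT model" is the element-wise opposite. The two
#' vectors represent extreme STAG2-loss-like and STAG2-proficient-like
#' phenotypes on the cohort's own expression scale (no per-gene z-scoring,
#' since the rule is defined on raw dataset values).
#'
#' @param expr Expression table: `gene_id` column plus one numeric column
#'   per sample.
#' @param signature Tibble (`gene_id`, `direction` in `"up"`/`"down"`), e.g.
#'   from [intersect_degs()].
#' @return Object of class `signature_model`: `genes` (tibble),
#'   `ko_centroid`, `wt_centroid` (named numeric vectors).
#' @export
build_signature_model <- function(expr, signature) {
  assert_cols(signature, c("gene_id", "direction"), "signature")
  if (!all(signature$direction %in% c("up", "down"))) {
    abort("signature directions must be 'up' or 'down'")
  }
  if (anyDuplicated(signature$gene_id)) abort("duplicated signature gene")
  m <- expr_matrix(expr)
  present <- signature$gene_id %in% rownames(m)
  if (!any(present)) abort("no signature gene is present in the cohort")
  if (any(!present)) {
    warn(sprintf("dropping %d signature gene(s) absent from the cohort",
                 sum(!present)))
  }
  sig <- as_tibble(signature)[present, ]
  sub <- m[sig$gene_id, , drop = FALSE]
  hi <- apply(sub, 1, max)
  lo <- apply(sub, 1, min)
  up <- sig$direction == "up"
  ko <- ifelse(up, hi, lo)
  wt <- ifelse(up, lo, hi)
  names(ko) <- names(wt) <- sig$gene_id
  structure(list(genes = sig, ko_centroid = ko, wt_centroid = wt),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d genes (%d up, %d down)\n",
              nrow(x$genes), sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down")))
  invisible(x)
}

#' Classify cohort samples against signature centroids
#'
#' Runs two-group k-means (Euclidean, Lloyd iterations to convergence) on
#' the signature-gene expression of each sample, with the two clusters
#' initialized at the KO-model and WT-model centroids. Samples ending up in
#' the cluster whose converged centroid lies nearer the KO model are
#' labeled `"signature-like"`, the rest `"signature-different"`. Distance
#' ties break toward the WT cluster (the conservative side). Given the
#' fixed initialization the procedure is deterministic.
#'
#' @param expr Expression table (`gene_id` + sample columns); extra
#'   non-signature genes are ignored.
#' @param model A [build_signature_model()] fit.
#' @param max_iter Lloyd iteration cap.
#' @return Object of class `cohort_classification` with `labels`
#'   (tibble: `sample_id`, `cluster`, `label`), the converged `centers`,
#'   and `iterations`. `tidy()` returns the labels, `glance()` group sizes.
#' @export
classify_cohort <- function(expr, model, max_iter = 100L) {
  if (!inherits(model, "signature_model")) abort("`model` must be a signature_model")
  m <- expr_matrix(expr)
  genes <- model$genes$gene_id
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("cohort lacks %d model gene(s), e.g. %s",
                  length(missing), paste(head(missing, 3), collapse = ", ")))
  }
  x <- t(m[genes, , drop = FALSE])  # samples x genes
  if (nrow(x) == 0) abort("empty cohort")
  centers <- rbind(ko = model$ko_centroid[genes], wt = model$wt_centroid[genes])

  sq_dist_to <- function(center) colSums((t(x) - center)^2)
  assign <- rep(NA_character_, nrow(x))
  it <- 0L
  repeat {
    it <- it + 1L
    d_ko <- sq_dist_to(centers["ko", ])
    d_wt <- sq_dist_to(centers["wt", ])
    new_assign <- ifelse(d_ko < d_wt, "ko", "wt")  # tie -> wt
    if (identical(new_assign, assign) || it > max_iter) {
      assign <- new_assign
      break
    }
    assign <- new_assign
    if (any(assign == "ko")) {
      centers["ko", ] <- colMeans(x[assign == "ko", , drop = FALSE])
    }
    if (any(assign == "wt")) {
      centers["wt", ] <- colMeans(x[assign == "wt", , drop = FALSE])
    }
  }
  # which converged cluster is nearer the KO model?
  d_to_ko_model <- c(
    ko = sum((centers["ko", ] - model$ko_centroid[genes])^2),
    wt = sum((centers["wt", ] - model$ko_centroid[genes])^2)
  )
  like_cluster <- names(which.min(d_to_ko_model))
  labels <- tibble(
    sample_id = rownames(x),
    cluster = assign,
    label = if_else(assign == like_cluster,
                    "signature-like", "signature-different")
  )
  structure(list(labels = labels, centers = centers, iterations = it,
                 like_cluster = like_cluster),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<cohort_classification> %s after %d Lloyd iteration(s)\n",
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$iterations))
  invisible(x)
}

#' @export
tidy.cohort_classification <- function(x, ...) x$labels

#' @export
glance.cohort_classification <- function(x, ...) {
  tibble(
    n = nrow(x$labels),
    n_signature_like = sum(x$labels$label == "signature-like"),
    n_signature_different = sum(x$labels$label == "signature-different"),
    iterations = x$iterations
  )
}

#' PCA projection of samples over signature genes
#'
#' Per-gene centered singular value decomposition of the samples-by-genes
#' matrix. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so projections are reproducible
#' across platforms.
#'
#' @param expr Expression table (`gene_id` + sample columns).
#' @param n_components Number of components to return.
#' @return Object of class `signature_pca`: `scores` tibble
#'   (`sample_id`, `PC1`, ...), `var_explained` (fractions of total
#'   variance, non-increasing), and `loadings`.
#' @export
pca_project <- function(expr, n_components = 2L) {
  m <- expr_matrix(expr)
  x <- t(m)
  if (nrow(x) < 2) abort("need at least two samples for PCA")
  if (all(apply(x, 2, sd) == 0)) abort("constant expression matrix")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      scores = bind_cols(tibble(sample_id = rownames(x)),
                         as_tibble(scores)),
      var_explained = var_frac[seq_len(k)],
      loadings = rot
    ),
    class = "signature_pca"
  )
}

#' @export
print.signature_pca <- function(x, ...) {
  cat(sprintf("<signature_pca> %d samples, %d component(s); variance: %s\n",
              nrow(x$scores), length(x$var_explained),
              paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.signature_pca <- function(x, ...) x$scores

#' Scatter plot of the first two PCA components
#' @param object A `signature_pca`.
#' @param labels Optional tibble (`sample_id`, `label`) to color points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_pca <- function(object, labels = NULL, ...) {
  dat <- object$scores
  if (!is.null(labels)) dat <- dat |> left_join(labels, by = "sample_id")
  p <- ggplot(dat, aes(x = .data$PC1, y = .data$PC2)) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    theme_minimal()
  if (!is.null(labels)) {
    p + geom_point(aes(color = .data$label))
  } else {
    p + geom_point()
  }
}
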
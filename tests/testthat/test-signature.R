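test_that("signature derivation keeps concordant significant genes only", {
  dp <- simulate_deg_pair(n_concordant = 50, n_discordant = 20, n_nonsig = 30,
                          seed = 1)
  sig <- intersect_degs(dp$deg_a, dp$deg_b)
  expect_equal(nrow(sig), 50)
  expect_setequal(sig$gene_id, dp$truth$gene_id)
  expect_equal(sig$direction[match(dp$truth$gene_id, sig$gene_id)],
               dp$truth$direction)

  # FDR exactly at the threshold is excluded; discordant genes are excluded
  a <- tibble::tibble(gene_id = c("x", "y"), log2fc = c(1, 1),
                      fdr = c(0.05, 0.01))
  b <- tibble::tibble(gene_id = c("x", "y"), log2fc = c(1, -1),
                      fdr = c(0.01, 0.01))
  expect_equal(nrow(intersect_degs(a, b)), 0)
})

test_that("centroid models take per-gene cohort extremes by direction", {
  expr <- tibble::tibble(gene_id = c("up1", "dn1", "flat"),
                         s1 = c(1, 7, 2), s2 = c(5, 3, 2))
  sig <- tibble::tibble(gene_id = c("up1", "dn1", "flat"),
                        direction = c("up", "down", "up"))
  m <- build_signature_model(expr, sig)
  expect_equal(unname(m$ko_centroid), c(5, 3, 2))
  expect_equal(unname(m$wt_centroid), c(1, 7, 2))

  # all-down signature mirrors the rule
  sig_dn <- tibble::tibble(gene_id = c("up1", "dn1"), direction = "down")
  m2 <- build_signature_model(expr, sig_dn)
  expect_equal(unname(m2$ko_centroid), c(1, 3))

  expect_warning(
    build_signature_model(expr, tibble::tibble(gene_id = c("up1", "zzz"),
                                               direction = "up")),
    "dropping"
  )
  expect_error(
    build_signature_model(expr, tibble::tibble(gene_id = "zzz",
                                               direction = "up")),
    "no signature gene"
  )
})

test_that("classifier recovers planted labels and matches stats::kmeans", {
  dp <- simulate_deg_pair(seed = 2)
  co <- simulate_cohort(n_patients = 150, n_genes = 400,
                        signature = dp$truth, noise_sd = 0, seed = 4)
  model <- build_signature_model(co$expression, dp$truth)
  cls <- classify_cohort(co$expression, model)
  expect_no_label_errors(tidy(cls), co$labels)

  # independent cross-check: Lloyd k-means from the same initial centroids
  x <- t(as.matrix(co$expression[-1]))[, match(model$genes$gene_id,
                                               co$expression$gene_id)]
  km <- suppressWarnings(stats::kmeans(
    x, centers = rbind(model$ko_centroid, model$wt_centroid),
    algorithm = "Lloyd", iter.max = 100
  ))
  like <- km$cluster == which.min(rowSums(
    (km$centers - rbind(model$ko_centroid, model$ko_centroid))^2
  ))
  expect_equal(tidy(cls)$label == "signature-like", unname(like))
})

test_that("classifier tolerates noise at the effect size", {
  dp <- simulate_deg_pair(seed = 5)
  co <- simulate_cohort(n_patients = 200, n_genes = 400,
                        signature = dp$truth, effect = 2, noise_sd = 2,
                        seed = 6)
  model <- build_signature_model(co$expression, dp$truth)
  acc <- mean(tidy(classify_cohort(co$expression, model))$label ==
                co$labels$group)
  expect_gte(acc, 0.9)
})

test_that("classification ignores extra genes and gene order", {
  withr::with_seed(17, {
    dp <- simulate_deg_pair(seed = 7)
    co <- simulate_cohort(n_patients = 80, n_genes = 200,
                          signature = dp$truth, noise_sd = 1, seed = 7)
    model <- build_signature_model(co$expression, dp$truth)
    base_labels <- tidy(classify_cohort(co$expression, model))

    shuffled <- co$expression[sample(nrow(co$expression)), ]
    expect_equal(tidy(classify_cohort(shuffled, model)), base_labels)

    extra <- dplyr::bind_rows(
      co$expression,
      tibble::tibble(gene_id = "unrelated") |>
        dplyr::bind_cols(as.data.frame(t(stats::setNames(
          rnorm(nrow(co$labels)), co$labels$sample_id))))
    )
    expect_equal(tidy(classify_cohort(extra, model)), base_labels)
  })
})

test_that("label assignment is symmetric under global sign flips", {
  dp <- simulate_deg_pair(seed = 8)
  co <- simulate_cohort(n_patients = 60, n_genes = 150,
                        signature = dp$truth, noise_sd = 1, seed = 8)
  model <- build_signature_model(co$expression, dp$truth)
  lab <- tidy(classify_cohort(co$expression, model))
  neg_expr <- co$expression
  neg_expr[-1] <- -neg_expr[-1]

  # negating expression alone swaps the two labels exactly
  neg_model <- build_signature_model(neg_expr, dp$truth)
  swapped <- tidy(classify_cohort(neg_expr, neg_model))
  expect_equal(swapped$label == "signature-like",
               lab$label == "signature-different")

  # negating expression and flipping directions preserves them
  flipped_sig <- dp$truth |>
    dplyr::mutate(direction = ifelse(direction == "up", "down", "up"))
  both <- tidy(classify_cohort(neg_expr,
                               build_signature_model(neg_expr, flipped_sig)))
  expect_equal(both$label, lab$label)
})

test_that("classifier accuracy does not increase with noise", {
  dp <- simulate_deg_pair(seed = 9)
  acc <- vapply(c(0, 1, 2, 4, 8), function(ns) {
    accs <- vapply(1:5, function(s) {
      co <- simulate_cohort(n_patients = 100, n_genes = 150,
                            signature = dp$truth, effect = 1.5, noise_sd = ns,
                            seed = s)
      model <- build_signature_model(co$expression, dp$truth)
      mean(tidy(classify_cohort(co$expression, model))$label ==
             co$labels$group)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.02))  # non-increasing up to seed jitter
  expect_equal(acc[1], 1)
})

test_that("single samples and ties resolve deterministically", {
  expr <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(9.4, 1.1))
  model <- structure(
    list(genes = tibble::tibble(gene_id = c("g1", "g2"),
                                direction = c("up", "down")),
         ko_centroid = c(g1 = 10, g2 = 1), wt_centroid = c(g1 = 0, g2 = 9)),
    class = "signature_model"
  )
  out <- tidy(classify_cohort(expr, model))
  expect_equal(out$label, "signature-like")  # nearer the KO model
  # exact tie breaks toward the WT cluster
  tie <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(5, 5))
  expect_equal(tidy(classify_cohort(tie, model))$label, "signature-different")
  expect_error(classify_cohort(expr[, 1], model), "empty cohort")
})

test_that("PCA projection separates planted groups with fixed signs", {
  dp <- simulate_deg_pair(seed = 10)
  co <- simulate_cohort(n_patients = 100, n_genes = 120,
                        signature = dp$truth, noise_sd = 0.5, seed = 10)
  sig_expr <- co$expression[co$expression$gene_id %in% dp$truth$gene_id, ]
  p <- pca_project(sig_expr)
  sc <- tidy(p) |> dplyr::left_join(co$labels, by = "sample_id")
  m1 <- mean(sc$PC1[sc$group == "signature-like"])
  m2 <- mean(sc$PC1[sc$group == "signature-different"])
  expect_gt(abs(m1 - m2), 2 * (stats::sd(sc$PC1[sc$group == "signature-like"]) +
                                 stats::sd(sc$PC1[sc$group == "signature-different"])))
  # variance fractions are non-increasing and sum below 1
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1)
  # duplicated samples project identically
  dup <- sig_expr
  dup$dup_of_1 <- dup[[2]]
  td2 <- tidy(pca_project(dup))
  expect_equal(unlist(td2[td2$sample_id == "dup_of_1", -1]),
               unlist(td2[td2$sample_id == names(sig_expr)[2], -1]),
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_project(sig_expr[, 1:2]), "two samples")
  const <- sig_expr
  const[-1] <- 1
  expect_error(pca_project(const), "constant")
})
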
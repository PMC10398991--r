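test_that("per-sample group means reduce to the constant for flat data", {
  beta <- matrix(0.5, nrow = 6, ncol = 6,
                 dimnames = list(sprintf("cg%02d", 1:6),
                                 sprintf("S%02d", 1:6)))
  ds <- methylation_dataset(
    beta, data.frame(sample_id = colnames(beta),
                     group = rep(c("normal", "tumor"), each = 3),
                     purity = c(NA, NA, NA, 0.5, 0.6, 0.7)))
  ann <- probe_annotation(
    data.frame(probe_id = rownames(beta), island = TRUE),
    data.frame(probe_id = rownames(beta),
               gene_id = rep(c("A", "B", "C"), each = 2),
               region = "TSS200"))
  calls <- gene_call_set(hyper = c("A", "B"), hypo = character(0),
                         tested = c("A", "B", "C"))
  fl <- fake_flags("A", c("A", "B", "C"))
  expect_warning(gm <- sample_group_means(ds, calls, fl, ann),
                 "empty gene group")
  expect_true(all(gm$mean_beta == 0.5))
  expect_setequal(unique(gm$group),
                  c("neural_hmg", "non_neural_hmg", "non_neural_nondm"))
  # single-probe group mean equals that probe's value
  ds$beta["cg05", ] <- 0.9  # gene C = non_neural_nondm, probes cg05/cg06
  expect_warning(gm2 <- sample_group_means(ds, calls, fl, ann),
                 "empty gene group")
  expect_equal(gm2$mean_beta[gm2$group == "non_neural_nondm"],
               rep(0.7, 3))
})

test_that("Huber fit is exact on clean lines and resists gross outliers", {
  x <- seq(0.1, 1, length.out = 20)
  fit <- robust_fit(2 * x + 1, x)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)

  # bounded noise below the Huber threshold: identical to OLS
  noise <- 0.04 * sin(seq_len(20) * 2.399)
  y <- 2 * x + 1 + noise
  fit2 <- robust_fit(y, x)
  ols <- lm(y ~ x)
  expect_equal(fit2$slope, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(fit2$intercept, unname(coef(ols)[1]), tolerance = 1e-8)

  # one gross outlier: Huber stays within 5% of the true slope, OLS drifts
  y3 <- y
  y3[5] <- y3[5] + 5
  fit3 <- robust_fit(y3, x)
  ols3 <- unname(coef(lm(y3 ~ x))[2])
  expect_lt(abs(fit3$slope - 2) / 2, 0.05)
  expect_gt(abs(ols3 - 2) / 2, 0.2)

  expect_error(robust_fit(rnorm(10), rep(0.4, 10)), "rank-deficient")
  expect_error(robust_fit(rnorm(3), rnorm(3)), ">= 5")
})

test_that("methylation-degree comparison runs and flags degenerate input", {
  u <- generate_universe(200, neural_fraction = 0.3, seed = 61)
  sim <- generate_methylation(u$annotation, u$truth$neural_genes,
                              n_hyper = 60, neural_enrichment = 0.5,
                              n_normal = 8, n_tumor = 8, seed = 62)
  dm <- diff_methylation(sim$dataset)
  calls <- aggregate_genes(dm, u$annotation)
  fl <- flag_genes(u$go, universe = u$truth$genes)
  res <- methylation_degree_compare(sim$dataset, calls, fl, u$annotation)
  expect_true(res$p >= 0 && res$p <= 1)
  expect_false(res$degenerate)
  expect_identical(nrow(res$summary), res$n_neural + res$n_non_neural)

  tiny_calls <- gene_call_set(
    hyper = c(intersect(calls$hyper, neural_gene_ids(fl))[1],
              setdiff(calls$hyper, neural_gene_ids(fl))[1]),
    hypo = character(0), tested = calls$tested)
  res1 <- methylation_degree_compare(sim$dataset, tiny_calls, fl,
                                     u$annotation)
  expect_true(res1$degenerate)
  expect_equal(res1$p, 1)
})

test_that("bivalency cross-tables conserve marginals and detect planted odds", {
  u <- generate_universe(2000, neural_fraction = 0.2,
                         bivalent_fraction = 0.2, seed = 63)
  w <- setNames(rep(1, 2000), u$truth$genes)
  w[u$truth$bivalent_genes] <- 3  # 3x hyper odds for bivalent genes
  sim <- generate_methylation(u$annotation, u$truth$neural_genes,
                              n_hyper = 300, neural_enrichment = NULL,
                              hyper_weight = w, n_normal = 10,
                              n_tumor = 10, seed = 64)
  dm <- diff_methylation(sim$dataset)
  calls <- aggregate_genes(dm, u$annotation)
  fl <- flag_genes(u$go, universe = u$truth$genes)
  bc <- bivalency_crosstab(calls, fl, u$truth$bivalent_genes)
  expect_equal(sum(bc$overall$table), length(calls$tested))
  expect_equal(sum(bc$bivalent$table) + sum(bc$non_bivalent$table),
               length(calls$tested))
  expect_gt(bc$overall$or, 1.5)
  expect_lt(bc$overall$p, 0.001)

  # no bivalent genes at all: bivalent stratum skipped with a warning
  w <- capture_warnings(bc2 <- bivalency_crosstab(calls, fl, character(0)))
  expect_true(any(grepl("empty stratum", w)))
  expect_null(bc2$bivalent)
  w2 <- capture_warnings(bivalency_crosstab(calls, fl, "NOT_IN_UNIVERSE"))
  expect_true(any(grepl("dropped", w2)))
})

test_that("hallmark enrichment is null-calibrated and BH-adjusted", {
  universe <- sprintf("G%04d", 1:800)
  # neural status exactly independent of hyper inside the hallmark
  idx <- 0:799
  hyper <- universe[idx %% 2 == 0]
  neural <- universe[(idx %/% 2) %% 4 == 0]
  calls <- gene_call_set(hyper, character(0), universe)
  fl <- fake_flags(neural, universe)
  hm <- hallmark_enrichment(calls, fl, gene_set_collection(
    list(h1 = universe[1:400])))
  expect_equal(hm$p, 1, tolerance = 1e-10)
  expect_equal(hm$p_adj, hm$p)  # single hallmark: FDR = p
  expect_true(all(hm$p_adj >= hm$p, na.rm = TRUE))

  expect_warning(
    hm2 <- hallmark_enrichment(calls, fl, gene_set_collection(
      list(h1 = universe[1:100], h_empty = "ZZZ"))),
    "empty tested intersection")
  expect_true(is.na(hm2$p[hm2$set_name == "h_empty"]))
})
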
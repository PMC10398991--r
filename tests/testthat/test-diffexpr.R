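test_that("without covariates or weights the DE stage equals the two-group moderated t", {
  genes <- sprintf("G%03d", 1:200)
  ex <- generate_expression(genes, diff_assoc = genes[1:20],
                            age_confounded = FALSE, seed = 71)
  de <- de_expression(ex$dataset, covariates = character(0),
                      use_precision_weights = FALSE)
  # independent route: group-mean fit plus the shared moderation engine
  y <- ex$dataset$log_expr
  i1 <- ex$dataset$samples$condition == "neuron"
  i2 <- !i1
  coef <- rowMeans(y[, i1]) - rowMeans(y[, i2])
  s2 <- (rowSums((y[, i1] - rowMeans(y[, i1]))^2) +
           rowSums((y[, i2] - rowMeans(y[, i2]))^2)) /
    (sum(i1) + sum(i2) - 2)
  eb <- ebayes_moderate(s2, sum(i1) + sum(i2) - 2, coef = coef,
                        stderr_unit = sqrt(1 / sum(i1) + 1 / sum(i2)))
  expect_equal(de$logFC, unname(coef), tolerance = 1e-10)
  expect_equal(de$t_mod, unname(eb$t_mod), tolerance = 1e-10)
  expect_equal(de$p, unname(eb$p), tolerance = 1e-10)
})

test_that("age/sex adjustment removes covariate-driven false positives", {
  genes <- sprintf("G%03d", 1:500)
  age_genes <- genes[1:50]
  ex <- generate_expression(genes, diff_assoc = character(0),
                            age_effect_genes = age_genes,
                            age_confounded = TRUE, seed = 72)
  de_adj <- de_expression(ex$dataset, covariates = c("age", "sex"))
  ur_adj <- suppressWarnings(classify_differentiation(de_adj))
  expect_lte(length(intersect(ur_adj, age_genes)),
             ceiling(0.05 * length(genes)))
  # unadjusted, the confounded age effect masquerades as an expression
  # shift of age_beta times the realized between-condition age gap;
  # adjustment removes it
  de_raw <- de_expression(ex$dataset, covariates = character(0))
  ia <- de_raw$gene_id %in% age_genes
  sheet <- ex$dataset$samples
  age_gap <- mean(sheet$age[sheet$condition == "neuron"]) -
    mean(sheet$age[sheet$condition == "progenitor"])
  expect_equal(mean(de_raw$logFC[ia]), 0.15 * age_gap, tolerance = 0.2)
  expect_lt(mean(abs(de_adj$logFC[ia])), 0.3)
})

test_that("rank-deficient designs fail naming the aliased column", {
  genes <- sprintf("G%03d", 1:50)
  ex <- generate_expression(genes, diff_assoc = character(0), seed = 73)
  ex$dataset$samples$age <- 55  # constant, aliased with the intercept
  expect_error(de_expression(ex$dataset, covariates = "age"),
               "rank-deficient.*age")
})

test_that("a constant expression matrix yields no differential calls", {
  y <- matrix(3, nrow = 20, ncol = 12,
              dimnames = list(sprintf("G%02d", 1:20),
                              sprintf("S%02d", 1:12)))
  ds <- expression_dataset(
    y, data.frame(sample_id = colnames(y),
                  condition = rep(c("progenitor", "neuron"), each = 6)))
  de <- de_expression(ds, covariates = character(0))
  expect_true(all(de$status == "nonDE"))
})

test_that("precision weights are positive and recover planted shifts", {
  genes <- sprintf("G%03d", 1:400)
  da <- genes[1:40]
  ex <- generate_expression(genes, diff_assoc = da, is_counts = TRUE,
                            age_confounded = FALSE, seed = 74)
  w <- neuromethyl:::voom_weights(
    ex$dataset$log_expr,
    model.matrix(~ factor(ex$dataset$samples$condition)))
  expect_true(all(w > 0 & is.finite(w)))
  de <- de_expression(ex$dataset, covariates = character(0))
  rec <- classify_differentiation(de)
  expect_gte(mean(da %in% rec), 0.9)
})

test_that("differentiation classification extracts exactly the UR genes", {
  de <- structure(
    data.frame(gene_id = sprintf("G%02d", 1:10),
               logFC = c(rep(2, 3), rep(-2, 2), rep(0, 5)),
               t_mod = 0, df_total = 10, p = 0.5, p_adj = 0.5,
               status = c(rep("UR", 3), rep("DR", 2), rep("nonDE", 5)),
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
  expect_identical(classify_differentiation(de), sprintf("G%02d", 1:3))
  de$status <- "nonDE"
  expect_warning(out <- classify_differentiation(de), "no differentiation")
  expect_length(out, 0L)
})

test_that("overlap shares, odds ratios and composition behave at the null", {
  universe <- sprintf("G%04d", 1:1000)
  idx <- 0:999
  hyper <- universe[idx %% 5 == 0]          # 20% hyper
  diff_assoc <- universe[(idx %/% 5) %% 2 == 0]  # independent of hyper
  calls <- gene_call_set(hyper, character(0), universe)
  fl <- fake_flags(universe[1:300], universe)
  ov <- overlap_stats(calls, diff_assoc, fl)
  row <- ov$shares[ov$shares$set == "diff_assoc", ]
  expect_equal(row$pct_hyper, 20, tolerance = 1e-10)
  expect_equal(row$or, 1, tolerance = 1e-10)
  expect_equal(row$p, 1, tolerance = 1e-10)

  # composition fractions always sum to one
  de <- structure(
    data.frame(gene_id = universe, logFC = 0, t_mod = 0, df_total = 10,
               p = 0.5, p_adj = 0.5,
               status = sample(c("DR", "UR", "nonDE"), 1000,
                               replace = TRUE),
               stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
  ov2 <- overlap_stats(calls, diff_assoc, fl, de_cancer = de)
  sums <- rowSums(ov2$expression[, c("frac_DR", "frac_UR", "frac_nonDE")])
  expect_equal(sums, rep(1, nrow(ov2$expression)))
})

test_that("planted hyper-differentiation coupling is recovered as an odds ratio", {
  set.seed(75)
  universe <- sprintf("G%05d", 1:20000)
  diff_assoc <- sample(universe, 4000)
  # hyper probability 3x higher for differentiation-associated genes
  p <- ifelse(universe %in% diff_assoc, 0.30, 0.10)
  hyper <- universe[runif(20000) < p]
  calls <- gene_call_set(hyper, character(0), universe)
  ov <- suppressWarnings(
    overlap_stats(calls, diff_assoc, fake_flags(character(0), universe)))
  or <- ov$shares$or[ov$shares$set == "diff_assoc"]
  true_or <- (0.3 / 0.7) / (0.1 / 0.9)
  expect_gt(or, true_or * 0.85)
  expect_lt(or, true_or * 1.15)
})
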
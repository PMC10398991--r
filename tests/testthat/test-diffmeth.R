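test_that("beta-to-M transform matches its closed form and is monotone", {
  expect_equal(beta_to_m(0.5, offset = 0), 0)
  expect_equal(beta_to_m(0.8, offset = 0), 2)
  expect_equal(beta_to_m(0.25, offset = 0), log2(1 / 3), tolerance = 1e-3)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
  expect_error(beta_to_m(1.5), "outside")
})

test_that("probewise fit reproduces exact and textbook two-sample results", {
  # exact means, zero variance
  beta <- matrix(m_to_beta(c(0, 0, 2, 2)), nrow = 1,
                 dimnames = list("cg1", c("N1", "N2", "T1", "T2")))
  ds <- methylation_dataset(
    beta, data.frame(sample_id = colnames(beta),
                     group = c("normal", "normal", "tumor", "tumor")))
  fw <- fit_probewise(ds, offset = 0)
  expect_equal(fw$logFC_m, 2)
  expect_equal(fw$s2, 0)

  # equal groups -> zero coefficient
  beta2 <- matrix(rep(c(0.3, 0.6), 2), nrow = 1,
                  dimnames = list("cg1", c("N1", "N2", "T1", "T2")))
  ds2 <- methylation_dataset(
    beta2, data.frame(sample_id = colnames(beta2),
                      group = c("normal", "normal", "tumor", "tumor")))
  expect_equal(fit_probewise(ds2, offset = 0)$logFC_m, 0)

  # random 5v5 probes against the pooled-formula oracle
  set.seed(31)
  beta3 <- matrix(runif(30 * 10, 0.05, 0.95), nrow = 30,
                  dimnames = list(sprintf("cg%02d", 1:30),
                                  sprintf("S%02d", 1:10)))
  ds3 <- methylation_dataset(
    beta3, data.frame(sample_id = colnames(beta3),
                      group = rep(c("normal", "tumor"), each = 5)))
  fw3 <- fit_probewise(ds3, offset = 0)
  m3 <- beta_to_m(beta3, offset = 0)
  for (i in c(1, 13, 30)) {
    orc <- pooled_t_oracle(m3[i, 6:10], m3[i, 1:5])
    expect_equal(fw3$logFC_m[i], orc$coef, tolerance = 1e-12)
    expect_equal(fw3$s2[i], orc$s2, tolerance = 1e-12)
  }
})

test_that("probes with insufficient non-missing samples are excluded", {
  ds <- tiny_meth()
  ds$beta["cg01", c("T1", "T2")] <- NA
  expect_message(fw <- fit_probewise(ds, offset = 0), "1 probe")
  expect_false("cg01" %in% fw$probe_id)
})

test_that("variance moderation handles the degenerate shrinkage limits", {
  set.seed(32)
  coef <- rnorm(20)
  # identical variances: complete shrinkage to the common value
  s2c <- rep(0.5, 20)
  eb <- ebayes_moderate(s2c, 10, coef = coef, stderr_unit = 0.6)
  expect_identical(eb$d0, Inf)
  expect_equal(eb$s0_sq, 0.5)
  expect_equal(eb$s_post_sq, s2c)
  expect_equal(eb$t_mod, coef / (sqrt(0.5) * 0.6))

  # d0 = 0: ordinary t exactly
  s2 <- rchisq(20, 5)
  eb0 <- ebayes_moderate(s2, 8, coef = coef, stderr_unit = 0.5, d0 = 0)
  expect_equal(eb0$t_mod, coef / (sqrt(s2) * 0.5))
  expect_equal(eb0$df_total, rep(8, 20))

  # posterior variance lies between the observed and prior variances
  set.seed(33)
  s2h <- 0.3 * 4 / rchisq(200, 4) * rchisq(200, 10) / 10
  ebh <- ebayes_moderate(s2h, 10)
  expect_true(all(ebh$s_post_sq >=
                    pmin(s2h, ebh$s0_sq) - 1e-12))
  expect_true(all(ebh$s_post_sq <=
                    pmax(s2h, ebh$s0_sq) + 1e-12))

  expect_warning(ebayes_moderate(rchisq(5, 3), 4), "fewer than 10")
})

test_that("the moderated-t stage agrees with an independent reference", {
  u <- generate_universe(80, seed = 34)
  sim <- generate_methylation(u$annotation, u$truth$neural_genes,
                              n_hyper = 10, n_normal = 6, n_tumor = 6,
                              seed = 35)
  dm <- diff_methylation(sim$dataset)
  m <- beta_to_m(sim$dataset$beta)
  design <- cbind(1, sim$dataset$samples$group == "tumor")
  fit <- limma::eBayes(limma::lmFit(m, design))
  eb <- attr(dm, "ebayes")
  expect_equal(eb$d0, unname(fit$df.prior), tolerance = 1e-8)
  expect_equal(eb$s0_sq, unname(fit$s2.prior), tolerance = 1e-8)
  expect_equal(dm$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(dm$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches hand-evaluated step-up results", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  p <- c(0.9, 0.001, 0.5)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("probe calls apply all three thresholds with strict inequalities", {
  expect_identical(call_probes(0.01, 1.5, 0.12), "hyper")
  expect_identical(call_probes(0.01, 1.5, 0.10), "ns")
  expect_identical(call_probes(0.06, 3, 0.3), "ns")
  expect_identical(call_probes(0.01, -1.5, -0.12), "hypo")
  expect_identical(call_probes(0.05, 1.5, 0.12), "ns")
  expect_identical(call_probes(NA, 1.5, 0.12), "ns")
})

test_that("gene aggregation follows the one-or-more promoter-probe rule", {
  probes <- data.frame(
    probe_id = sprintf("cg%02d", 1:7),
    island = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  map <- data.frame(
    probe_id = sprintf("cg%02d", 1:7),
    gene_id = c("A", "A", "A", "A", "B", "B", "C"),
    region = c("TSS200", "Body", "TSS1500", "1stExon",
               "TSS200", "TSS200", "Body"))
  ann <- probe_annotation(probes, map)
  dm <- data.frame(
    probe_id = sprintf("cg%02d", 1:7),
    call = c("hyper", "hyper", "ns", "ns", "hyper", "hypo", "hyper"))
  gc <- aggregate_genes(dm, ann)
  # A: one hyper TSS200 probe among ns probes -> hyper
  expect_true("A" %in% gc$hyper)
  # B: hyper and hypo promoter probes -> both sets
  expect_true("B" %in% gc$hyper && "B" %in% gc$hypo)
  # C: only a Body probe is hyper -> not in background nor calls
  expect_false("C" %in% gc$tested)
  expect_setequal(gc$tested, c("A", "B"))

  # island restriction removes non-island promoter probes
  gc_isl <- aggregate_genes(dm, ann, island_only = TRUE)
  expect_true("A" %in% gc_isl$hyper)
  dm2 <- dm
  dm2$call[1] <- "ns"  # cg01 was A's only island hyper promoter probe
  dm2$call[3] <- "hyper"  # cg03: promoter but non-island
  expect_false("A" %in% aggregate_genes(dm2, ann,
                                        island_only = TRUE)$hyper)
  expect_true("A" %in% aggregate_genes(dm2, ann)$hyper)

  # order independence
  shuf <- dm[sample(nrow(dm)), ]
  gc_s <- aggregate_genes(shuf, ann)
  expect_setequal(gc_s$hyper, gc$hyper)
  expect_setequal(gc_s$tested, gc$tested)
})

test_that("stronger planted effects never reduce the hyper-call count", {
  u <- generate_universe(150, seed = 36)
  n_calls <- vapply(c(1.5, 2.5, 4), function(eff) {
    sim <- generate_methylation(u$annotation, u$truth$neural_genes,
                                n_hyper = 25, effect_m = eff,
                                n_normal = 8, n_tumor = 8, seed = 37)
    sum(diff_methylation(sim$dataset)$call == "hyper")
  }, 0)
  expect_true(all(diff(n_calls) >= 0))
})
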
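test_that("boundary variance collapse reproduces ordinary least squares", {
  set.seed(1)
  n <- 40
  pat <- rep(1:20, each = 2)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)    # no patient effect at all
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_lmm(y, X, pat, "ML")
  ols <- lm.fit(X, y)$coefficients
  if (fit$random_intercept_variance == 0)
    expect_equal(fit$fixed_effects, ols, tolerance = 1e-8)
  # whether or not the boundary is hit, estimates stay close to OLS here
  expect_equal(unname(fit$fixed_effects), unname(ols), tolerance = 0.05)
})

test_that("balanced paired design recovers the mean within-patient difference", {
  set.seed(2)
  n <- 30
  pat <- rep(seq_len(n), each = 2)
  t2 <- rep(c(0, 1), n)
  y <- 2 + 0.8 * t2 + rnorm(n, 0, 0.6)[pat] + rnorm(2 * n, 0, 0.3)
  X <- cbind(`(Intercept)` = 1, time = t2)
  fit <- fit_lmm(y, X, pat, "ML")
  paired_diff <- mean(y[t2 == 1] - y[t2 == 0])
  expect_equal(unname(fit$fixed_effects[["time"]]), paired_diff,
               tolerance = 1e-8)
})

test_that("fits agree with the reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(3)
  n <- 50
  pat <- rep(seq_len(n), each = 3)
  tt <- factor(rep(c("T1", "T2", "T3"), n))
  pur <- runif(3 * n, 0.2, 0.9)
  y <- 1 - 0.5 * pur + 0.7 * (tt == "T2") - 0.2 * (tt == "T3") +
    rnorm(n, 0, 0.5)[pat] + rnorm(3 * n, 0, 0.4)
  X <- cbind(`(Intercept)` = 1, purity = pur, t2 = as.numeric(tt == "T2"),
             t3 = as.numeric(tt == "T3"))
  for (crit in c("ML", "REML")) {
    ours <- fit_lmm(y, X, pat, crit)
    ref <- lme4::lmer(y ~ pur + tt + (1 | pat), REML = crit == "REML")
    expect_equal(unname(ours$fixed_effects), unname(lme4::fixef(ref)),
                 tolerance = 1e-5)
    expect_equal(ours$log_likelihood, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-5)
    vc <- as.data.frame(lme4::VarCorr(ref))
    expect_equal(ours$random_intercept_variance, vc$vcov[1], tolerance = 1e-4)
    expect_equal(ours$residual_variance, vc$vcov[2], tolerance = 1e-4)
  }
})

test_that("variance components are recovered from simulated data", {
  cfg <- simulation_config(n_patients = 200, n_genes = 50,
                           signature_blocks = c(immune = 2),
                           effect_sizes = list(immune = list()),
                           random_intercept_sd = 0.5, residual_sd = 0.5,
                           pcr_rate = 0, dropout_rule = 0, seed = 4)
  ch <- simulate_cohort(cfg)
  cl <- ch$clinical
  X <- cbind(`(Intercept)` = 1, purity = cl$purity)
  ests <- t(apply(log2(ch$expression), 1, function(y) {
    f <- fit_lmm(y, X, cl$patient_id, "REML")
    c(f$random_intercept_variance, f$residual_variance)
  }))
  expect_lt(abs(mean(ests[, 1]) - 0.25) / 0.25, 0.15)
  expect_lt(abs(mean(ests[, 2]) - 0.25) / 0.25, 0.15)
})

test_that("likelihood-ratio machinery behaves at its edges", {
  set.seed(5)
  pat <- rep(1:10, each = 2)
  y <- rnorm(20)
  X <- cbind(`(Intercept)` = rep(1, 20))
  f <- fit_lmm(y, X, pat, "ML")
  same <- lrt_time(f, f)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)

  X3 <- cbind(`(Intercept)` = 1, t2 = rep(c(0, 1), 10),
              t3 = rep(c(0, 0), 10))
  expect_error(fit_lmm(y, X3, pat, "ML"), "aliased")   # t3 aliased w/ nothing varying

  Xf <- cbind(`(Intercept)` = 1, t2 = rep(c(0, 1), 10))
  ff <- fit_lmm(y, Xf, pat, "ML")
  lrt <- lrt_time(ff, f)
  expect_equal(lrt$df, 1)
  expect_error(lrt_time(f, fit_lmm(y, Xf, pat, "REML")), "ML")
  # monotonicity of likelihood under nesting
  expect_gte(ff$log_likelihood, f$log_likelihood - 1e-8)
})

test_that("run_de recovers a planted effect with the right sign", {
  cfg <- simulation_config(n_patients = 60, n_genes = 30,
                           signature_blocks = c(immune = 10),
                           effect_sizes = list(
                             immune = list(time = c(T2 = 1))),
                           random_intercept_sd = 0.2, residual_sd = 0.2,
                           pcr_rate = 0, dropout_rule = 0, seed = 6)
  ch <- simulate_cohort(cfg)
  de <- run_de(log_transform(ch$expression), ch$clinical,
               comparisons = list(c("T1", "T2")))
  imm <- ch$truth$gene_effects$block == "immune"
  imm_genes <- ch$truth$gene_effects$gene_id[imm]
  hits <- de[de$feature %in% imm_genes, ]
  # T2 higher than T1 gives positive estimates near the planted +1
  expect_true(all(hits$estimate > 0.6 & hits$estimate < 1.2))
  expect_true(all(hits$p_value < 0.01))
  flat <- de[!de$feature %in% imm_genes, ]
  expect_true(all(abs(flat$estimate) < 0.2))
})

test_that("gene selection applies both thresholds as a union over rows", {
  res <- data.frame(
    feature = c("a", "a", "b", "c"),
    group = "overall", comparison = c("T1-T2", "T2-T3", "T1-T2", "T1-T2"),
    estimate = c(0.5, 1.5, 0.5, 2.0),
    t_statistic = 1, lrt_chisq = 1,
    p_value = c(0.005, 0.005, 0.005, 0.5), fdr = 0.1)
  expect_identical(select_de_genes(res), "a")   # passes in one comparison
  res$p_value[4] <- 0.001
  expect_setequal(select_de_genes(res), c("a", "c"))
})

test_that("consensus clustering recovers planted temporal archetypes", {
  cfg <- simulation_config(n_patients = 40, n_genes = 60,
                           signature_blocks = c(up_down = 20, down_up = 20,
                                                mono = 20),
                           effect_sizes = list(
                             up_down = list(time = c(T2 = 2, T3 = -1)),
                             down_up = list(time = c(T2 = -2, T3 = 1)),
                             mono = list(time = c(T2 = 1, T3 = 2))),
                           random_intercept_sd = 0.2, residual_sd = 0.3,
                           pcr_rate = 0, dropout_rule = 0, seed = 8)
  ch <- simulate_cohort(cfg)
  cc <- consensus_kmeans(log_transform(ch$expression), ch$clinical, k = 3,
                         n_resamples = 30, seed = 1)
  truth <- ch$truth$gene_effects$block
  expect_gt(ari(cc$labels, truth), 0.9)
  # consensus matrix structure
  expect_true(isSymmetric(cc$consensus))
  expect_true(all(diag(cc$consensus) == 1))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
})

test_that("duplicate gene rows always co-cluster with consensus 1", {
  cfg <- quiet_config(n_patients = 10, n_genes = 12, seed = 9)
  cfg$residual_sd <- 0.5
  ch <- simulate_cohort(cfg)
  expr <- log_transform(ch$expression)
  expr["G0002", ] <- expr["G0001", ]
  cc <- consensus_kmeans(expr, ch$clinical, k = 3, n_resamples = 20, seed = 2)
  expect_identical(unname(cc$labels["G0001"]), unname(cc$labels["G0002"]))
  expect_equal(cc$consensus["G0001", "G0002"], 1)
})

test_that("pathway-to-cluster mapping enforces both FDR gates", {
  enr <- data.frame(pathway = c("P1", "P2", "P3"), cluster = "C1",
                    fdr = c(0.10, 0.25, 0.10))
  de <- data.frame(feature = c("P1", "P2", "P3"), group = "overall",
                   comparison = "T1-T2", estimate = 1, t_statistic = 1,
                   lrt_chisq = 1, p_value = 0.001,
                   fdr = c(0.01, 0.01, 0.06))
  m <- map_pathways_to_clusters(enr, de)
  expect_identical(m, c(P1 = "C1"))
})
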
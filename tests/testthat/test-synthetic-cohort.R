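test_that("degenerate no-signal config yields constant genes", {
  cfg <- quiet_config()
  ch <- simulate_cohort(cfg)
  # zero purity effect, zero noise: every gene constant across all samples
  expect_true(all(apply(ch$expression, 1, function(x) diff(range(x))) == 0))
})

test_that("a planted time effect forces the exact expression ratio", {
  cfg <- simulation_config(n_patients = 8, n_genes = 20,
                           signature_blocks = c(immune = 5),
                           effect_sizes = list(immune = list(time = c(T2 = 1))),
                           random_intercept_sd = 0, residual_sd = 0,
                           pcr_rate = 0, dropout_rule = 0, seed = 2)
  ch <- simulate_cohort(cfg)
  cl <- ch$clinical
  imm <- ch$truth$gene_effects$gene_id[ch$truth$gene_effects$block == "immune"]
  for (p in unique(cl$patient_id)) {
    s1 <- cl$sample_id[cl$patient_id == p & cl$time == "T1"]
    s2 <- cl$sample_id[cl$patient_id == p & cl$time == "T2"]
    # no purity/noise terms planted: the T2/T1 ratio is exactly 2
    expect_equal(unname(ch$expression[imm[1], s2] / ch$expression[imm[1], s1]),
                 2, tolerance = 1e-12)
  }
})

test_that("patient-mean residual variance follows the law of total variance", {
  cfg <- simulation_config(n_patients = 60, n_genes = 10,
                           signature_blocks = c(immune = 2),
                           effect_sizes = list(immune = list()),
                           random_intercept_sd = 0.5, residual_sd = 0.5,
                           pcr_rate = 0, dropout_rule = 0, seed = 1)
  ch <- simulate_cohort(cfg)
  l2 <- log2(ch$expression)
  cl <- ch$clinical
  # no fixed effects: per-patient mean of (log2 - baseline) = b_i + mean(eps)
  vs <- apply(l2 - 5, 1, function(y) var(tapply(y, cl$patient_id, mean)))
  expected <- 0.25 + 0.25 / 3
  expect_lt(abs(mean(vs) - expected) / expected, 0.2)
})

test_that("same seed gives bit-identical outputs for all generators", {
  cfg <- simulation_config(n_patients = 10, n_genes = 15,
                           signature_blocks = c(immune = 3), seed = 7)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  sig <- synthetic_signature_matrix()
  expect_identical(simulate_mixtures(sig, 5, 0.5, seed = 7),
                   simulate_mixtures(sig, 5, 0.5, seed = 7))
  expect_identical(simulate_histology_image(300, 300, 5, 3, seed = 7),
                   simulate_histology_image(300, 300, 5, 3, seed = 7))
})

test_that("noise-free generation is exactly invertible by per-gene OLS", {
  cfg <- simulation_config(n_patients = 25, n_genes = 8,
                           signature_blocks = c(immune = 4),
                           effect_sizes = list(
                             immune = list(purity = -2, time = c(T2 = 1, T3 = -0.5))),
                           random_intercept_sd = 0, residual_sd = 0,
                           pcr_rate = 0, dropout_rule = 0, seed = 5)
  ch <- simulate_cohort(cfg)
  cl <- ch$clinical
  y <- log2(ch$expression["G0001", ])
  fit <- lm(y ~ purity + subtype + time, data = cl)
  expect_equal(unname(coef(fit)[["purity"]]), -2, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[["timeT2"]]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[["timeT3"]]), -0.5, tolerance = 1e-8)
})

test_that("pCR patients never have a T3 sample", {
  ch <- simulate_cohort(simulation_config(n_patients = 60, n_genes = 5,
                                          signature_blocks = c(immune = 2),
                                          seed = 11))
  cl <- ch$clinical
  pcr_pat <- unique(cl$patient_id[cl$pcr == "pCR"])
  expect_gt(length(pcr_pat), 0)
  expect_false(any(cl$patient_id %in% pcr_pat & cl$time == "T3"))
})

test_that("mixture fractions live on the simplex and follow the signature", {
  sig <- synthetic_signature_matrix()
  mx <- simulate_mixtures(sig, 50, noise_sd = 0.05 * mean(sig), seed = 7)
  expect_true(all(mx$fractions >= 0 & mx$fractions <= 1))
  expect_equal(unname(rowSums(mx$fractions)), rep(1, 50), tolerance = 1e-12)

  # forced pure fraction with no noise reproduces the signature column
  f <- matrix(0, 1, ncol(sig)); f[1, 1] <- 1
  pure <- simulate_mixtures(sig, 1, 0, seed = 1, fractions = f)
  expect_equal(unname(pure$mixture[, 1]), unname(sig[, 1]))

  # no-noise mixtures are exactly signature %*% fractions
  mx0 <- simulate_mixtures(sig, 5, 0, seed = 3)
  expect_equal(mx0$mixture, sig %*% t(mx0$fractions),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(simulate_mixtures(sig, 5, -1), "noise_sd")
})

test_that("histology generator plants the requested cells with valid areas", {
  blank <- simulate_histology_image(512, 512, 0, 0, seed = 1)
  expect_equal(nrow(blank$truth), 0)
  expect_true(all(blank$image > 0.5))

  sim <- simulate_histology_image(1024, 1024, 40, 20, seed = 3)
  ly <- sim$truth[sim$truth$type == "lymphocyte", ]
  expect_equal(nrow(ly), 40)
  expect_true(all(ly$area >= 60 & ly$area <= 150))
  oth <- sim$truth[sim$truth$type == "other", ]
  expect_equal(nrow(oth), 20)
  expect_true(all(oth$area > 200))

  expect_error(simulate_histology_image(50, 50, 100, 0), "too small")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(subtype_proportions = c(A = 0.5, B = 0.4)),
               "sum to 1")
  expect_error(simulation_config(residual_sd = -1), "sds")
  expect_error(simulation_config(n_genes = 5,
                                 signature_blocks = c(immune = 10)),
               "smaller")
})
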
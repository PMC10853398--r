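test_that("generation is deterministic and degenerate configs give zero deltas", {
  cfg <- small_cohort_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort$values, b$cohort$values)
  expect_identical(a$truth, b$truth)

  cfg0 <- small_cohort_config(seed = 5, effect_map = list(), noise_sd = 0,
                              insulin_reversion_rate = 0)
  gen0 <- generate_cohort(cfg0)
  d <- compute_deltas(gen0$cohort)
  expect_true(all(abs(d$delta) < 1e-9))
})

test_that("planted effect reproduces the closed-form feature-delta correlation", {
  # delta = s_y (b z_f + e), e ~ N(0, 0.2^2)  =>  cor = b / sqrt(b^2 + 0.04)
  cfg <- cohort_config(n_subjects = 1000, n_proteins = 5, n_metabolites = 5,
                       n_clinical = 6,
                       effect_map = list(HbA1c = c(prot_0001 = 0.5)),
                       noise_sd = 0.2, insulin_reversion_rate = 0,
                       seed = 101)
  gen <- generate_cohort(cfg)
  d <- compute_deltas(gen$cohort, "HbA1c")
  d6 <- d[d$horizon == "6mo", ]
  x <- gen$cohort$values$t0[d6$subject_id, "prot_0001"]
  r_obs <- cor(x, d6$delta)
  r_theory <- 0.5 / sqrt(0.5^2 + 0.2^2)
  # 95% CI via Fisher transform at n = 1000
  z <- atanh(r_obs)
  ci <- tanh(z + c(-1.96, 1.96) / sqrt(1000 - 3))
  expect_gt(r_theory, ci[1])
  expect_lt(r_theory, ci[2])
})

test_that("HOMA-IR equals glucose x insulin / 405 at every timepoint", {
  gen <- generate_cohort(small_cohort_config(seed = 7))
  for (tp in c("t0", "t1", "t2")) {
    m <- gen$cohort$values[[tp]]
    ok <- !is.na(m[, "glucose"]) & !is.na(m[, "insulin"])
    expect_equal(m[ok, "HOMA_IR"], m[ok, "glucose"] * m[ok, "insulin"] / 405,
                 tolerance = 1e-9)
  }
})

test_that("OLS on noiseless deltas recovers the planted coefficients", {
  em <- list(HbA1c = c(prot_0001 = 0.4, prot_0002 = -0.25, met_0001 = 0.3))
  cfg <- cohort_config(n_subjects = 200, n_proteins = 6, n_metabolites = 6,
                       n_clinical = 6, effect_map = em, noise_sd = 0,
                       insulin_reversion_rate = 0, seed = 13)
  gen <- generate_cohort(cfg)
  t0 <- gen$cohort$values$t0
  z <- scale(t0[, names(em$HbA1c)])
  s_y <- sd(t0[, "HbA1c"])
  fit <- lm(gen$truth$noiseless_deltas$HbA1c / s_y ~ z - 1)
  expect_equal(unname(coef(fit)), unname(em$HbA1c), tolerance = 1e-6)
})

test_that("planting an effect on HOMA-IR or an unknown feature is rejected", {
  expect_error(small_cohort_config(effect_map = list(HOMA_IR = c(prot_0001 = 0.3))),
               "HOMA_IR")
  cfg <- small_cohort_config(effect_map = list(HbA1c = c(prot_9999 = 0.3)))
  expect_error(generate_cohort(cfg), "not in the registry")
})

test_that("missingness injection is MCAR at the configured rates and only masks", {
  cfg <- cohort_config(n_subjects = 500, n_proteins = 10, n_metabolites = 5,
                       n_clinical = 6,
                       missing_rates = c(protein = 0.05), seed = 77)
  gen <- generate_cohort(cfg)
  masked <- inject_missingness(gen$cohort, cfg)

  # conservation: observed cells unchanged
  for (tp in c("t0", "t1", "t2")) {
    obs <- !is.na(masked$values[[tp]])
    expect_identical(masked$values[[tp]][obs], gen$cohort$values[[tp]][obs])
  }
  # rate within the binomial 99% CI over the 10,000 t0/t1 protein cells
  prot <- masked$features$kind == "protein"
  cells <- c(masked$values$t0[, prot], masked$values$t1[, prot])
  n_cells <- length(cells)
  expect_identical(n_cells, 10000L)
  phat <- mean(is.na(cells))
  half <- 2.576 * sqrt(0.05 * 0.95 / n_cells)
  expect_gt(phat, 0.05 - half)
  expect_lt(phat, 0.05 + half)

  # identity at rate zero, saturation at rate one
  cfg0 <- cohort_config(n_subjects = 30, n_proteins = 4, n_metabolites = 4,
                        n_clinical = 6, missing_rates = c(protein = 0),
                        seed = 3)
  gen0 <- generate_cohort(cfg0)
  expect_identical(inject_missingness(gen0$cohort, cfg0)$values,
                   gen0$cohort$values)
  cfg1 <- cohort_config(n_subjects = 30, n_proteins = 4, n_metabolites = 4,
                        n_clinical = 6, missing_rates = c(metabolite = 1),
                        seed = 3)
  gen1 <- generate_cohort(cfg1)
  m1 <- inject_missingness(gen1$cohort, cfg1)
  met <- m1$features$kind == "metabolite"
  expect_true(all(is.na(m1$values$t0[, met])))
  expect_true(all(is.na(m1$values$t1[, met])))
})

test_that("masking is deterministic given the seed", {
  cfg <- small_cohort_config(seed = 21,
                             missing_rates = c(metabolite = 0.2))
  gen <- generate_cohort(cfg)
  expect_identical(inject_missingness(gen$cohort, cfg)$values,
                   inject_missingness(gen$cohort, cfg)$values)
})
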
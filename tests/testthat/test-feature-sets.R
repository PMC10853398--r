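test_that("feature sets follow the nested design and always carry the baseline", {
  cfg <- small_cohort_config(seed = 1)
  co <- generate_cohort(cfg)$cohort
  sets <- build_feature_sets(co$features, "glucose")
  expect_setequal(names(sets),
                  c("baseline", "demographics_only", "clinical_selected",
                    "clinical_full", "proteomics", "metabolomics", "all"))
  for (s in sets) expect_true("glucose" %in% s)
  expect_identical(sets$baseline, "glucose")
  expect_setequal(sets$demographics_only, c("glucose", "age", "sex", "BMI"))
  expect_lte(length(sets$clinical_selected), 16)  # 15 variables + baseline
  expect_setequal(sets$all,
                  unique(c(sets$clinical_full, sets$proteomics,
                           sets$metabolomics)))
  expect_error(build_feature_sets(co$features, "not_a_feature"))
})

test_that("paired folds are identical across sets, so equal sets score equally", {
  cfg <- cohort_config(n_subjects = 120, n_proteins = 8, n_metabolites = 8,
                       n_clinical = 6, seed = 31)
  co <- generate_cohort(cfg)$cohort
  d <- binarize_deltas(compute_deltas(co))
  sets <- list(proteomics = c("HbA1c", sprintf("prot_%04d", 1:8)),
               duplicate = c("HbA1c", sprintf("prot_%04d", 1:8)),
               demographics_only = c("HbA1c", "age", "sex", "BMI"))
  ev <- evaluate_feature_sets(co, d, "HbA1c", "6mo", feature_sets = sets,
                              seed = 9)
  expect_identical(ev$reports$proteomics$fold_assignment,
                   ev$reports$demographics_only$fold_assignment)
  expect_identical(ev$reports$proteomics$scores, ev$reports$duplicate$scores)
  expect_identical(ev$reports$proteomics$coef, ev$reports$duplicate$coef)
})

test_that("planted protein effects make proteomics beat demographics (paired)", {
  cfg <- cohort_config(
    n_subjects = 400, n_proteins = 20, n_metabolites = 10, n_clinical = 6,
    effect_map = list(HbA1c = c(prot_0001 = 0.5, prot_0002 = 0.5,
                                prot_0003 = 0.4)),
    noise_sd = 0.4, seed = 17)
  co <- generate_cohort(cfg)$cohort
  d <- binarize_deltas(compute_deltas(co))
  sets <- build_feature_sets(co$features, "HbA1c")
  ev <- evaluate_feature_sets(co, d, "HbA1c", "6mo",
                              feature_sets = sets[c("demographics_only",
                                                    "proteomics")],
                              seed = 3)
  paired_diff <- ev$reports$proteomics$scores -
    ev$reports$demographics_only$scores
  expect_gt(mean(paired_diff, na.rm = TRUE), 0)
})

test_that("mean-reverting insulin drives a negative baseline coefficient", {
  cfg <- cohort_config(n_subjects = 400, n_proteins = 5, n_metabolites = 5,
                       n_clinical = 6, effect_map = list(),
                       insulin_reversion_rate = 0.3, seed = 23)
  co <- generate_cohort(cfg)$cohort
  d <- binarize_deltas(compute_deltas(co))
  sets <- build_feature_sets(co$features, "insulin")["baseline"]
  ev <- evaluate_feature_sets(co, d, "insulin", "6mo", feature_sets = sets,
                              seed = 4)
  expect_true(all(ev$reports$baseline$coef["insulin", ] < 0))
})

test_that("feature ranking orders by mean |coefficient| with id tie-breaks", {
  rep_ <- structure(list(
    task = list(mode = "classification", n_folds = 2),
    coef = matrix(c(0.5, 0.3, -0.4, -0.4, 0, 0, 0.1, 0.7), 4, 2,
                  dimnames = list(c("p_b", "p_a", "p_zero", "p_mix"), NULL)),
    feature_summary = data.frame(
      feature = c("p_b", "p_a", "p_zero", "p_mix"),
      kind = "protein",
      mean_abs_coef = c(0.4, 0.4, 0, 0.4),
      mean_coef = c(0.4, -0.4, 0, 0.3),
      coef_min = c(0.3, -0.4, 0, 0),
      coef_max = c(0.5, -0.4, 0, 0.7),
      nonzero_folds = c(2L, 2L, 0L, 1L),
      stringsAsFactors = FALSE)), class = "cv_model_report")
  rk <- rank_features(rep_, k = 3)
  # all tied at 0.4: ordered by feature id; the all-zero feature is unranked
  expect_identical(rk$feature, c("p_a", "p_b", "p_mix"))
  expect_warning(rk_all <- rank_features(rep_, k = 10), "nonzero")
  expect_identical(nrow(rk_all), 3L)
})

test_that("planted proteins are recovered in the top-10 ranking", {
  eff <- setNames(rep(0.45, 10), sprintf("prot_%04d", 1:10))
  cfg <- cohort_config(n_subjects = 600, n_proteins = 40, n_metabolites = 10,
                       n_clinical = 6, effect_map = list(HbA1c = eff),
                       noise_sd = 0.6, seed = 29)
  co <- generate_cohort(cfg)$cohort
  d <- binarize_deltas(compute_deltas(co))
  sets <- build_feature_sets(co$features, "HbA1c")["proteomics"]
  ev <- evaluate_feature_sets(co, d, "HbA1c", "6mo", feature_sets = sets,
                              seed = 2)
  rk <- rank_features(ev$reports$proteomics, k = 10)
  expect_gte(length(intersect(rk$feature, names(eff))), 8)
})
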
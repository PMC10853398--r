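#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the shape and statistical structure of a simulated wellness-cohort
#' dataset: subjects measured at intake (t0), ~6 months (t1) and — for a
#' follow-up subset — ~1 year (t2), with demographic, clinical-lab, protein
#' and metabolite features, and *planted* sparse effects of baseline features
#' on the changes of the five clinical targets (see [clinical_targets()]).
#'
#' Changes are generated from a linear-Gaussian model on z-scored baseline
#' features: for target \eqn{y} with baseline standard deviation \eqn{s_y},
#' \deqn{\Delta y = s_y (\sum_f \beta_f z(x_f) + \gamma_y z(y_0) + \epsilon),
#'       \quad \epsilon \sim N(0, \mathrm{noise\_sd}^2),}
#' so effect sizes are standardized (target-SD change per feature-SD).
#' For insulin \eqn{\gamma = -}`insulin_reversion_rate`, a regression-to-the-
#' mean dynamic: high baseline insulin tends to fall. HOMA-IR is always
#' derived as glucose x insulin / 405 at every timepoint, so effects planted
#' directly on `HOMA_IR` are a configuration error — drive it through its
#' parents instead.
#'
#' @param n_subjects Number of subjects (all have t0 and t1).
#' @param n_proteins,n_metabolites Numbers of omic features.
#' @param n_clinical Number of clinical-lab features *including* the five
#'   targets; the three demographics (age, sex, BMI) are separate.
#' @param followup_1y_fraction Fraction of subjects with a t2 (1-year) visit.
#' @param effect_map Named list, target -> named numeric vector of
#'   standardized effects, e.g. `list(HbA1c = c(prot_0001 = 0.4))`. `NULL`
#'   (the default) uses [default_effect_map()] restricted to the features
#'   the configuration actually generates; an explicit empty `list()`
#'   plants no effects.
#' @param noise_sd Per-target delta noise SD in baseline-SD units; a single
#'   number is recycled to all targets.
#' @param insulin_reversion_rate Magnitude of the negative baseline-insulin
#'   coefficient in the insulin delta model, in `[0, 1]`.
#' @param missing_rates Named vector of missing-completely-at-random rates per
#'   feature kind (`demographic`, `clinical`, `protein`, `metabolite`).
#' @param baseline_params Named list target -> `c(mean, sd)` for baseline
#'   clinical values; defaults approximate a generally healthy US wellness
#'   cohort (HbA1c 5.5%, glucose 93 mg/dL, insulin 10.7 uIU/mL, eGFR 90).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1131L,
                          n_proteins = 262L,
                          n_metabolites = 710L,
                          n_clinical = 67L,
                          followup_1y_fraction = 639 / 1131,
                          effect_map = NULL,
                          noise_sd = 0.6,
                          insulin_reversion_rate = 0.3,
                          missing_rates = c(demographic = 0,
                                            clinical = 0.001,
                                            protein = 0.0005,
                                            metabolite = 0.02),
                          baseline_params = list(
                            HbA1c = c(5.51, 0.43),
                            glucose = c(93.2, 12.2),
                            insulin = c(10.7, 7.3),
                            eGFR = c(90.2, 15.2)
                          ),
                          seed = 1L) {
  stopifnot(n_subjects >= 1, n_proteins >= 0, n_metabolites >= 0,
            n_clinical >= 5)
  if (followup_1y_fraction < 0 || followup_1y_fraction > 1)
    stop("followup_1y_fraction must be in [0, 1]")
  if (insulin_reversion_rate < 0 || insulin_reversion_rate > 1)
    stop("insulin_reversion_rate must be in [0, 1]")
  kinds <- c("demographic", "clinical", "protein", "metabolite")
  mr <- rep(0, 4); names(mr) <- kinds
  mr[names(missing_rates)] <- missing_rates
  if (any(mr < 0 | mr > 1)) stop("missing_rates must be in [0, 1]")
  targets <- clinical_target_names()
  ns <- if (length(noise_sd) == 1) stats::setNames(rep(noise_sd, 5), targets)
        else noise_sd
  if (!all(targets %in% names(ns))) stop("noise_sd must cover all targets")
  if (any(ns < 0)) stop("noise_sd must be non-negative")
  if (is.null(effect_map)) {
    # default planted effects, restricted to the features this config has
    avail <- c(sprintf("prot_%04d", seq_len(n_proteins)),
               sprintf("met_%04d", seq_len(n_metabolites)))
    effect_map <- lapply(default_effect_map(),
                         function(e) e[names(e) %in% avail])
    effect_map <- effect_map[vapply(effect_map, length, 0L) > 0]
  }
  effect_map <- lapply(effect_map, function(e) {
    stopifnot(is.numeric(e), !is.null(names(e)))
    e
  })
  if (length(effect_map) && !all(names(effect_map) %in% targets))
    stop("effect_map names must be clinical targets")
  if ("HOMA_IR" %in% names(effect_map))
    stop("HOMA_IR deltas are derived from glucose and insulin; ",
         "plant effects on its parents instead")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_proteins = as.integer(n_proteins),
    n_metabolites = as.integer(n_metabolites),
    n_clinical = as.integer(n_clinical),
    followup_1y_fraction = followup_1y_fraction,
    effect_map = effect_map,
    noise_sd = ns,
    insulin_reversion_rate = insulin_reversion_rate,
    missing_rates = mr,
    baseline_params = baseline_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_effect_map <- function() {
  list(
    HbA1c   = c(prot_0001 = 0.40, prot_0002 = 0.40, met_0001 = 0.30),
    glucose = c(met_0002 = 0.40, prot_0003 = 0.30),
    eGFR    = c(prot_0004 = 0.40, met_0003 = 0.30),
    insulin = c(prot_0005 = 0.30)
  )
}

feature_registry <- function(config) {
  targets <- clinical_targets()
  n_lab <- config$n_clinical - nrow(targets)
  rbind(
    data.frame(feature_id = c("age", "sex", "BMI"), kind = "demographic",
               units = c("years", "0/1", "kg/m2"), stringsAsFactors = FALSE),
    data.frame(feature_id = targets$target, kind = "clinical",
               units = targets$units, stringsAsFactors = FALSE),
    if (n_lab > 0)
      data.frame(feature_id = sprintf("clin_%04d", seq_len(n_lab)),
                 kind = "clinical", units = "au", stringsAsFactors = FALSE),
    if (config$n_proteins > 0)
      data.frame(feature_id = sprintf("prot_%04d", seq_len(config$n_proteins)),
                 kind = "protein", units = "au", stringsAsFactors = FALSE),
    if (config$n_metabolites > 0)
      data.frame(feature_id = sprintf("met_%04d", seq_len(config$n_metabolites)),
                 kind = "metabolite", units = "au", stringsAsFactors = FALSE)
  )
}

new_cohort_table <- function(subjects, features, values) {
  stopifnot(identical(names(values), c("t0", "t1", "t2")))
  for (tp in names(values)) {
    stopifnot(nrow(values[[tp]]) == nrow(subjects),
              nrow(subjects) == 0 ||
                identical(rownames(values[[tp]]), subjects$subject_id),
              identical(colnames(values[[tp]]), features$feature_id))
  }
  structure(list(subjects = subjects, features = features, values = values),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  kinds <- table(x$features$kind)
  cat("<cohort_table> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$has_t2), " with 1-year follow-up), ",
      nrow(x$features), " features [",
      paste(names(kinds), kinds, sep = ":", collapse = ", "), "]\n", sep = "")
  na_counts <- vapply(x$values, function(m) sum(is.na(m)), 0)
  cat("  missing cells: t0 ", na_counts[["t0"]], ", t1 ", na_counts[["t1"]],
      ", t2 ", na_counts[["t2"]], "\n", sep = "")
  invisible(x)
}

# z-score a vector against its own sample mean/sd (generator-internal)
.zcol <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic longitudinal multiomic cohort
#'
#' Draws baseline (t0) values for all features, then generates per-horizon
#' changes of the clinical targets from the planted linear-Gaussian model in
#' [cohort_config()] and derives t1/t2 values by adding those changes to t0.
#' HOMA-IR is recomputed from glucose and insulin at each timepoint. The
#' output contains no missing values; use [inject_missingness()] afterwards.
#'
#' Follow-up values of glucose, insulin, HbA1c and eGFR are floored at 0.1
#' so relative-change binarization stays well defined for all subjects.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cohort` (a `cohort_table`) and `truth`
#'   (class `planted_truth`: the effect map plus the noiseless per-subject
#'   deltas, in target units, per target and horizon).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 50, n_proteins = 10, n_metabolites = 10,
#'                      n_clinical = 8, seed = 7)
#' gen <- generate_cohort(cfg)
#' gen$cohort
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  features <- feature_registry(config)
  planted <- unique(unlist(lapply(config$effect_map, names)))
  missing_feat <- setdiff(planted, features$feature_id)
  if (length(missing_feat))
    stop("effect_map references features not in the registry: ",
         paste(missing_feat, collapse = ", "))

  set.seed(config$seed)
  n <- config$n_subjects
  subject_id <- sprintf("S%05d", seq_len(n))
  age <- pmax(18, pmin(90, round(stats::rnorm(n, 49.5, 11.3))))
  sex <- stats::rbinom(n, 1, 0.5)
  bmi <- pmax(17, stats::rnorm(n, 27.6, 6.0))
  n_t2 <- round(config$followup_1y_fraction * n)
  has_t2 <- logical(n)
  has_t2[sample.int(n, n_t2)] <- TRUE
  subjects <- data.frame(subject_id, age, sex, bmi, has_t2,
                         stringsAsFactors = FALSE)

  p <- nrow(features)
  t0 <- matrix(NA_real_, n, p, dimnames = list(subject_id, features$feature_id))
  t0[, "age"] <- age; t0[, "sex"] <- sex; t0[, "BMI"] <- bmi
  for (tg in names(config$baseline_params)) {
    pr <- config$baseline_params[[tg]]
    t0[, tg] <- pmax(0.1, stats::rnorm(n, pr[1], pr[2]))
  }
  t0[, "HOMA_IR"] <- homa_ir(t0[, "glucose"], t0[, "insulin"])
  other <- features$feature_id[!(features$feature_id %in%
    c("age", "sex", "BMI", clinical_target_names()))]
  if (length(other))
    t0[, other] <- matrix(stats::rnorm(n * length(other)), n)

  # planted deltas for the four primary targets; HOMA-IR is derived
  primary <- c("HbA1c", "glucose", "insulin", "eGFR")
  horizons <- c("6mo", "1yr")
  noiseless <- list()
  delta <- list(`6mo` = list(), `1yr` = list())
  for (tg in primary) {
    s_y <- stats::sd(t0[, tg])
    eff <- config$effect_map[[tg]]
    gamma <- if (tg == "insulin") -config$insulin_reversion_rate else 0
    lin <- rep(0, n)
    if (length(eff))
      for (f in names(eff)) lin <- lin + eff[[f]] * .zcol(t0[, f])
    lin <- lin + gamma * .zcol(t0[, tg])
    noiseless[[tg]] <- s_y * lin
    for (h in horizons)
      delta[[h]][[tg]] <- s_y * (lin + config$noise_sd[[tg]] *
                                   stats::rnorm(n))
  }

  mk_followup <- function(h) {
    v <- t0
    for (tg in primary) v[, tg] <- pmax(0.1, t0[, tg] + delta[[h]][[tg]])
    v[, "HOMA_IR"] <- homa_ir(v[, "glucose"], v[, "insulin"])
    # small measurement drift on non-target features
    if (length(other)) {
      sds <- apply(t0[, other, drop = FALSE], 2, stats::sd)
      v[, other] <- t0[, other] +
        sweep(matrix(stats::rnorm(n * length(other)), n), 2, sds * 0.1, `*`)
    }
    v
  }
  t1 <- mk_followup("6mo")
  t2 <- mk_followup("1yr")
  t2[!has_t2, ] <- NA_real_

  cohort <- new_cohort_table(subjects, features,
                             list(t0 = t0, t1 = t1, t2 = t2))
  truth <- structure(list(
    effects = config$effect_map,
    insulin_reversion_rate = config$insulin_reversion_rate,
    noiseless_deltas = noiseless
  ), class = "planted_truth")
  list(cohort = cohort, truth = truth)
}

#' Mask values completely at random, by feature kind
#'
#' Replaces observed values with `NA` at the per-kind rates in
#' `config$missing_rates`, independently across cells (MCAR). Existing values
#' are never altered, only masked; structurally absent t2 rows (subjects
#' without a 1-year visit) are untouched.
#'
#' @param cohort A `cohort_table`.
#' @param config The [cohort_config()] carrying `missing_rates` and `seed`.
#' @param protect_targets If `TRUE` (default) the five clinical targets are
#'   never masked at t0 or t1, mirroring a cohort selected for complete
#'   outcome data at the first two visits.
#' @return The masked `cohort_table`.
#' @export
inject_missingness <- function(cohort, config, protect_targets = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(config, "cohort_config"))
  set.seed(config$seed + 1000003L)
  kinds <- cohort$features$kind
  targets <- clinical_target_names()
  for (tp in c("t0", "t1", "t2")) {
    m <- cohort$values[[tp]]
    for (kd in unique(kinds)) {
      rate <- config$missing_rates[[kd]]
      if (rate <= 0) next
      cols <- which(kinds == kd)
      mask <- matrix(stats::runif(nrow(m) * length(cols)) < rate,
                     nrow(m), length(cols))
      if (protect_targets && tp %in% c("t0", "t1"))
        mask[, colnames(m)[cols] %in% targets] <- FALSE
      m[, cols][mask] <- NA_real_
    }
    cohort$values[[tp]] <- m
  }
  cohort
}
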
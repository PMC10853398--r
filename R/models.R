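#' Train-fold z-score normalization
#'
#' Centers and scales columns by the *training* rows' mean and standard
#' deviation, then applies those statistics to any other rows — the held-out
#' fold never contributes to the normalization. Zero-variance training
#' columns are mapped to all-zeros with a warning.
#'
#' @param train Numeric matrix of training rows.
#' @param apply_to Matrix to transform with the training statistics
#'   (defaults to `train` itself).
#' @return The transformed `apply_to` matrix, with attributes `center` and
#'   `scale` carrying the training statistics.
#' @export
zscore_transform <- function(train, apply_to = train) {
  stopifnot(is.matrix(train), nrow(train) > 0,
            identical(colnames(train), colnames(apply_to)))
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  const <- scl == 0 | is.na(scl)
  if (any(const)) {
    warning("zero-variance column(s) mapped to zeros: ",
            paste(utils::head(colnames(train)[const], 5), collapse = ", "))
    scl[const] <- 1
    ctr[const] <- train[1, const]  # so constant columns become exactly 0
  }
  out <- sweep(sweep(apply_to, 2, ctr, `-`), 2, scl, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Seeded (optionally stratified) cross-validation folds
#'
#' @param n Number of observations.
#' @param k Number of folds.
#' @param labels Optional binary labels; when given, folds are stratified so
#'   each fold has a near-equal class mix.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1:k`.
#' @export
make_cv_folds <- function(n, k = 10L, labels = NULL, seed = 1L) {
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(labels)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(labels) == n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

f1_score <- function(truth, pred) {
  if (length(unique(truth)) < 2) return(NA_real_)
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

r2_score <- function(truth, pred) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / ss_tot
}

# one L1 fit with inner 5-fold penalty selection on the training fold only
fit_l1_inner <- function(x_train, y_train, mode, seed, lambda = NULL) {
  family <- if (mode == "classification") "binomial" else "gaussian"
  inner <- make_cv_folds(nrow(x_train), k = 5L,
                         labels = if (mode == "classification") y_train,
                         seed = seed)
  cv <- glmnet::cv.glmnet(x_train, y_train, family = family, alpha = 1,
                          standardize = FALSE, foldid = inner,
                          lambda = lambda)
  cv
}

#' Cross-validated L1-regularized prediction of clinical changes
#'
#' Fits, per outer fold, an L1-penalized linear (regression on the delta) or
#' logistic (classification of the binarized delta) model: predictors are
#' z-scored with training-fold statistics, the penalty is selected by inner
#' 5-fold cross-validation over a logarithmic grid on the training fold only,
#' and the score — held-out R-squared for regression, positive-class F1 for
#' classification — is computed on the held-out fold. Coefficients (on the
#' z-scored scale) are retained per fold, giving the per-feature mean,
#' range and nonzero-fold count used for predictor ranking.
#'
#' @param x Numeric predictor matrix (subjects x features), raw scale.
#' @param y Numeric response: binary labels (classification) or deltas
#'   (regression).
#' @param mode `"classification"` or `"regression"`.
#' @param n_folds Number of outer folds (default 10).
#' @param seed Seed controlling fold assignment and inner CV.
#' @param folds Optional precomputed outer fold vector (from
#'   [make_cv_folds()]); lets several feature sets share one fold
#'   assignment for paired comparison.
#' @param feature_kinds Optional character vector (parallel to the columns
#'   of `x`) recording each feature's kind, used by [rank_features()].
#' @param lambda Optional explicit penalty grid passed to glmnet.
#' @return A `cv_model_report`: task descriptor, per-fold train/test ids,
#'   coefficient matrix (features x folds), intercepts, per-fold scores with
#'   mean and SD, and a per-feature summary data.frame.
#' @export
cross_validated_fit <- function(x, y,
                                mode = c("classification", "regression"),
                                n_folds = 10L, seed = 1L, folds = NULL,
                                feature_kinds = NULL, lambda = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) >= n_folds)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%03d", seq_len(ncol(x)))
  if (mode == "classification" && length(unique(y)) < 2)
    stop("classification requires both classes present")
  if (is.null(folds))
    folds <- make_cv_folds(nrow(x), n_folds,
                           labels = if (mode == "classification") y,
                           seed = seed)
  n_folds <- max(folds)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))

  coefs <- matrix(0, ncol(x), n_folds,
                  dimnames = list(colnames(x), paste0("fold", seq_len(n_folds))))
  intercepts <- numeric(n_folds)
  scores <- rep(NA_real_, n_folds)
  fold_ids <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    x_tr <- zscore_transform(x[tr, , drop = FALSE])
    x_te <- zscore_transform(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    # single-column glmnet is unsupported; pad with a zero column
    pad <- ncol(x) == 1
    if (pad) {
      x_tr <- cbind(x_tr, .pad = 0)
      x_te <- cbind(x_te, .pad = 0)
    }
    cv <- fit_l1_inner(x_tr, y[tr], mode, seed = seed + 7919L * f,
                       lambda = lambda)
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    intercepts[f] <- cf[1]
    coefs[, f] <- if (pad) cf[2] else cf[-1]
    if (mode == "classification") {
      prob <- as.numeric(stats::predict(cv, newx = x_te, s = "lambda.min",
                                        type = "response"))
      sc <- f1_score(y[!tr], as.integer(prob >= 0.5))
      if (is.na(sc))
        warning("fold ", f, ": held-out fold has a single class; ",
                "F1 undefined and excluded from the mean")
      scores[f] <- sc
    } else {
      pred <- as.numeric(stats::predict(cv, newx = x_te, s = "lambda.min"))
      scores[f] <- r2_score(y[!tr], pred)
    }
    fold_ids[[f]] <- list(train = ids[tr], test = ids[!tr])
  }
  feature_summary <- data.frame(
    feature = colnames(x),
    kind = if (is.null(feature_kinds)) NA_character_ else feature_kinds,
    mean_coef = rowMeans(coefs),
    mean_abs_coef = rowMeans(abs(coefs)),
    coef_min = apply(coefs, 1, min),
    coef_max = apply(coefs, 1, max),
    nonzero_folds = as.integer(rowSums(coefs != 0)),
    stringsAsFactors = FALSE)
  structure(list(
    task = list(mode = mode, n_folds = n_folds),
    folds = fold_ids, fold_assignment = folds,
    coef = coefs, intercept = intercepts,
    scores = scores,
    score_mean = mean(scores, na.rm = TRUE),
    score_sd = stats::sd(scores[!is.na(scores)]),
    feature_summary = feature_summary
  ), class = "cv_model_report")
}

#' @export
print.cv_model_report <- function(x, ...) {
  cat("<cv_model_report> mode=", x$task$mode, ", ", x$task$n_folds,
      " folds\n  score: mean ", signif(x$score_mean, 4), " (sd ",
      signif(x$score_sd, 4), ")\n  nonzero features (any fold): ",
      sum(x$feature_summary$nonzero_folds > 0), "/",
      nrow(x$feature_summary), "\n", sep = "")
  invisible(x)
}

#' Predictor feature sets for trajectory prediction
#'
#' Builds the seven nested predictor groups compared by the pipeline:
#' `baseline` (only the predicted variable's own t0 value),
#' `demographics_only` (age, sex, BMI), `clinical_selected` (a configurable
#' 15-variable clinical/demographic subset associated with type 2 diabetes),
#' `clinical_full` (all clinical and demographic variables), `proteomics`,
#' `metabolomics`, and `all`. Every set additionally includes the baseline
#' value of the predicted target.
#'
#' @param features Feature registry data.frame (`feature_id`, `kind`).
#' @param target The predicted clinical target.
#' @param clinical_selected Optional id vector for the selected-clinical set;
#'   by default the five targets, age, sex, BMI and the first clinical labs
#'   of the registry, up to 15 variables.
#' @return Named list of feature-id vectors.
#' @export
build_feature_sets <- function(features, target,
                               clinical_selected = NULL) {
  stopifnot(target %in% features$feature_id)
  id <- features$feature_id
  demo <- id[features$kind == "demographic"]
  clin <- id[features$kind == "clinical"]
  prot <- id[features$kind == "protein"]
  met <- id[features$kind == "metabolite"]
  if (is.null(clinical_selected)) {
    base_sel <- c(clinical_target_names(), demo)
    extra <- setdiff(clin, base_sel)
    clinical_selected <- c(base_sel,
                           utils::head(extra, max(0, 15 - length(base_sel))))
  }
  with_base <- function(v) unique(c(target, v))
  sets <- list(
    baseline = with_base(character()),
    demographics_only = with_base(demo),
    clinical_selected = with_base(intersect(clinical_selected, id)),
    clinical_full = with_base(c(demo, clin)),
    proteomics = with_base(prot),
    metabolomics = with_base(met),
    all = with_base(c(demo, clin, prot, met))
  )
  empty <- names(sets)[vapply(sets, length, 0L) == 0]
  if (length(empty)) stop("empty feature set(s): ",
                          paste(empty, collapse = ", "))
  sets
}

#' Compare feature sets on one prediction task with paired folds
#'
#' Builds the predictor matrix from intake (t0) values of the subjects that
#' have a delta record for the requested target and horizon, makes a single
#' fold assignment, and runs [cross_validated_fit()] once per feature set on
#' those shared folds, so per-fold scores are directly comparable across
#' sets.
#'
#' @param cohort Preprocessed `cohort_table` (no missing values).
#' @param deltas A labeled `delta_table` (see [binarize_deltas()]).
#' @param target,horizon The prediction task (`horizon` in `"6mo"`, `"1yr"`).
#' @param feature_sets Named list of feature-id vectors (default
#'   [build_feature_sets()]).
#' @param mode `"classification"` (labels) or `"regression"` (deltas).
#' @param n_folds,seed Passed to the fold maker.
#' @return A list with `reports` (named list of `cv_model_report`) and
#'   `scores` (tidy data.frame: feature_set, fold, score).
#' @export
evaluate_feature_sets <- function(cohort, deltas, target,
                                  horizon = c("6mo", "1yr"),
                                  feature_sets = NULL,
                                  mode = c("classification", "regression"),
                                  n_folds = 10L, seed = 1L) {
  horizon <- match.arg(horizon)
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(feature_sets))
    feature_sets <- build_feature_sets(cohort$features, target)
  rec <- deltas[deltas$target == target & deltas$horizon == horizon, ,
                drop = FALSE]
  if (!nrow(rec)) stop("no delta records for ", target, " at ", horizon)
  sub_idx <- match(rec$subject_id, cohort$subjects$subject_id)
  stopifnot(!anyNA(sub_idx))
  x_all <- cohort$values$t0[sub_idx, , drop = FALSE]
  y <- if (mode == "classification") rec$label else rec$delta
  if (mode == "classification" && anyNA(y))
    stop("labels missing; run binarize_deltas() first")
  folds <- make_cv_folds(nrow(x_all), n_folds,
                         labels = if (mode == "classification") y,
                         seed = seed)
  reports <- list()
  tidy <- list()
  for (fs in names(feature_sets)) {
    cols <- feature_sets[[fs]]
    missing_cols <- setdiff(cols, colnames(x_all))
    if (length(missing_cols)) stop("feature set '", fs, "' references ",
                                   "unknown features: ",
                                   paste(missing_cols, collapse = ", "))
    rep_fs <- cross_validated_fit(
      x_all[, cols, drop = FALSE], y, mode = mode, seed = seed,
      folds = folds,
      feature_kinds = cohort$features$kind[match(cols,
                                                 cohort$features$feature_id)])
    rep_fs$task$target <- target
    rep_fs$task$horizon <- horizon
    rep_fs$task$feature_set <- fs
    reports[[fs]] <- rep_fs
    tidy[[fs]] <- data.frame(feature_set = fs,
                             fold = seq_along(rep_fs$scores),
                             score = rep_fs$scores,
                             stringsAsFactors = FALSE)
  }
  list(reports = reports,
       scores = do.call(rbind, c(tidy, list(make.row.names = FALSE))))
}

#' Rank model predictors by cross-fold coefficient weight
#'
#' Ranks features of the requested kind by mean absolute standardized
#' coefficient across folds (descending), breaking ties by feature id.
#' Features whose coefficient is zero in every fold are not ranked; if fewer
#' than `k` nonzero features exist, all are returned with a warning.
#'
#' @param report A `cv_model_report`.
#' @param k How many predictors to return (default 10).
#' @param restrict_kind Feature kind to rank (default `"protein"`); `NULL`
#'   ranks all features except the target's own baseline.
#' @return Data.frame with rank, feature, kind, mean absolute coefficient,
#'   coefficient range across folds, and nonzero-fold count.
#' @export
rank_features <- function(report, k = 10L, restrict_kind = "protein") {
  stopifnot(inherits(report, "cv_model_report"))
  fs <- report$feature_summary
  if (!is.null(restrict_kind)) {
    if (all(is.na(fs$kind)))
      stop("report carries no feature kinds; refit with feature_kinds=")
    fs <- fs[fs$kind %in% restrict_kind, , drop = FALSE]
  }
  fs <- fs[fs$nonzero_folds > 0, , drop = FALSE]
  if (nrow(fs) < k) {
    warning("only ", nrow(fs), " nonzero feature(s) available; returning all")
    k <- nrow(fs)
  }
  ord <- order(-fs$mean_abs_coef, fs$feature)
  out <- fs[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
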
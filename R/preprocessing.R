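# which timepoints a subject attends: t0/t1 always, t2 only with follow-up
attended_tps <- function(cohort, i)
  c("t0", "t1", if (cohort$subjects$has_t2[i]) "t2")

# stack a subject's rows over timepoints into one matrix (tps x features)
subject_block <- function(cohort, i, tps)
  do.call(rbind, lapply(tps, function(tp) cohort$values[[tp]][i, , drop = FALSE]))

drop_subjects <- function(cohort, ids) {
  keep <- !(cohort$subjects$subject_id %in% ids)
  cohort$subjects <- cohort$subjects[keep, , drop = FALSE]
  cohort$values <- lapply(cohort$values, function(m) m[keep, , drop = FALSE])
  cohort
}

drop_features <- function(cohort, ids) {
  keep <- !(cohort$features$feature_id %in% ids)
  cohort$features <- cohort$features[keep, , drop = FALSE]
  cohort$values <- lapply(cohort$values, function(m) m[, keep, drop = FALSE])
  cohort
}

# step 3: features (clinical/protein/metabolite) with missing fraction above
# the threshold, pooled over the first two timepoints across all subjects
step_feature_missingness <- function(cohort, threshold) {
  pooled <- rbind(cohort$values$t0, cohort$values$t1)
  frac <- colMeans(is.na(pooled))
  drop <- cohort$features$feature_id[
    frac > threshold & cohort$features$kind != "demographic"]
  drop
}

# step 4: subjects with >threshold missingness in remaining metabolites, or
# ANY missingness in remaining proteins/clinical, over attended timepoints
step_subject_missingness <- function(cohort, threshold) {
  kinds <- cohort$features$kind
  met <- kinds == "metabolite"
  strict <- kinds %in% c("protein", "clinical")
  bad <- vapply(seq_len(nrow(cohort$subjects)), function(i) {
    blk <- subject_block(cohort, i, attended_tps(cohort, i))
    met_frac <- if (any(met)) mean(is.na(blk[, met, drop = FALSE])) else 0
    met_frac > threshold || anyNA(blk[, strict, drop = FALSE])
  }, logical(1))
  cohort$subjects$subject_id[bad]
}

new_filter_report <- function() structure(list(steps = list()),
                                          class = "filter_report")

add_step <- function(report, name, subjects = character(),
                     features = character()) {
  report$steps[[length(report$steps) + 1]] <- list(
    step = name,
    subjects_removed = as.character(subjects),
    features_removed = as.character(features))
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (s in x$steps)
    cat(sprintf("  %-28s -%d subjects, -%d features\n", s$step,
                length(s$subjects_removed), length(s$features_removed)))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(
    step = vapply(x$steps, `[[`, "", "step"),
    subjects_removed = vapply(x$steps, function(s) length(s$subjects_removed), 0L),
    features_removed = vapply(x$steps, function(s) length(s$features_removed), 0L),
    stringsAsFactors = FALSE)
}

#' Serialize a filter report to JSON
#' @param report A `filter_report` from [run_preprocessing()].
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report$steps, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Preprocessing cascade for a longitudinal multiomic cohort
#'
#' Applies, in order: (1) keep only subjects with demographic, clinical,
#' proteomic and metabolomic data at two or more timepoints; (2) drop
#' subjects missing any of the five clinical targets at the first two
#' timepoints; (3) drop clinical/protein/metabolite features whose missing
#' fraction over the first two timepoints exceeds
#' `missing_feature_threshold`; (4) drop subjects with more than
#' `missing_subject_threshold` missingness in the remaining metabolites, or
#' any missingness in the remaining proteins or clinical labs; (5) impute the
#' remaining metabolite gaps with [impute_metabolites()]; (6) drop subjects
#' whose clinical values exceed `outlier_limits` at any attended timepoint.
#' The returned cohort contains no missing values, and the report records
#' exactly which subjects/features each step removed. Step order matters —
#' filtering features before subjects can save subjects whose missingness
#' was concentrated in dropped features — so the order is fixed.
#'
#' @param cohort A `cohort_table`.
#' @param missing_feature_threshold,missing_subject_threshold Missingness
#'   fractions above which a feature (step 3) or subject (step 4) is dropped.
#' @param outlier_limits Named numeric vector of upper limits on clinical
#'   values; subjects exceeding any limit at any attended timepoint are
#'   removed after imputation.
#' @param impute Set `FALSE` to skip step 5 (for cohorts known complete).
#' @param impute_max_iter,impute_n_trees Passed to [impute_metabolites()].
#' @param seed Seed for the imputation forests.
#' @return A list with `cohort` (filtered, imputed) and `report`
#'   (a `filter_report`).
#' @export
run_preprocessing <- function(cohort,
                              missing_feature_threshold = 0.10,
                              missing_subject_threshold = 0.10,
                              outlier_limits = c(HbA1c = 12, glucose = 200,
                                                 insulin = 60),
                              impute = TRUE,
                              impute_max_iter = 10L,
                              impute_n_trees = 100L,
                              seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  targets <- clinical_target_names()
  missing_targets <- setdiff(targets, cohort$features$feature_id)
  if (length(missing_targets))
    stop("clinical target(s) absent from the feature registry: ",
         paste(missing_targets, collapse = ", "))
  report <- new_filter_report()
  kinds_all <- c("demographic", "clinical", "protein", "metabolite")

  # step 1: all four data kinds present at >= 2 timepoints
  kinds <- cohort$features$kind
  present_kinds <- function(blk_row)
    vapply(kinds_all, function(kd) {
      cols <- kinds == kd
      any(cols) && any(!is.na(blk_row[cols]))
    }, logical(1))
  n_tp_complete <- vapply(seq_len(nrow(cohort$subjects)), function(i) {
    sum(vapply(attended_tps(cohort, i), function(tp)
      all(present_kinds(cohort$values[[tp]][i, ])), logical(1)))
  }, integer(1))
  rm1 <- cohort$subjects$subject_id[n_tp_complete < 2]
  cohort <- drop_subjects(cohort, rm1)
  report <- add_step(report, "two_timepoint_availability", subjects = rm1)

  # step 2: complete clinical targets at t0 and t1
  tmiss <- is.na(cohort$values$t0[, targets, drop = FALSE]) |
    is.na(cohort$values$t1[, targets, drop = FALSE])
  rm2 <- cohort$subjects$subject_id[rowSums(tmiss) > 0]
  cohort <- drop_subjects(cohort, rm2)
  report <- add_step(report, "complete_targets_t0_t1", subjects = rm2)

  # step 3: feature missingness filter
  rm3 <- step_feature_missingness(cohort, missing_feature_threshold)
  cohort <- drop_features(cohort, rm3)
  report <- add_step(report, "feature_missingness", features = rm3)
  if (!all(targets %in% cohort$features$feature_id))
    stop("a clinical target was removed by the feature filter; ",
         "lower its missingness or protect it upstream")

  # step 4: subject missingness filter
  rm4 <- step_subject_missingness(cohort, missing_subject_threshold)
  cohort <- drop_subjects(cohort, rm4)
  report <- add_step(report, "subject_missingness", subjects = rm4)

  # step 5: metabolite imputation
  if (impute && any(vapply(cohort$values, anyNA, logical(1))))
    cohort <- impute_metabolites(cohort, max_iter = impute_max_iter,
                                 n_trees = impute_n_trees, seed = seed)
  report <- add_step(report, "metabolite_imputation")

  # step 6: clinical outlier limits at any attended timepoint
  over <- vapply(seq_len(nrow(cohort$subjects)), function(i) {
    blk <- subject_block(cohort, i, attended_tps(cohort, i))
    any(vapply(names(outlier_limits), function(v)
      v %in% colnames(blk) &&
        any(blk[, v] > outlier_limits[[v]], na.rm = TRUE), logical(1)))
  }, logical(1))
  rm6 <- cohort$subjects$subject_id[over]
  cohort <- drop_subjects(cohort, rm6)
  report <- add_step(report, "clinical_outlier_limits", subjects = rm6)

  list(cohort = cohort, report = report)
}

#' Iterative random-forest imputation of metabolite gaps
#'
#' Missing metabolite values are initialized at per-feature medians, then
#' refined by repeatedly regressing each incomplete metabolite on all other
#' features with a random-forest regressor (over all attended
#' subject-timepoint rows) and refreshing the imputed cells, in order of
#' increasing missingness. Iteration stops when the relative change in the
#' imputed values falls below 1e-3, when it stops decreasing, or at
#' `max_iter`. Observed values are never modified. The forests are seeded
#' and single-threaded, so results are reproducible.
#'
#' @param cohort A `cohort_table` whose only missing values are metabolites.
#' @param max_iter Iteration cap.
#' @param n_trees Trees per forest.
#' @param seed Integer seed.
#' @return The cohort with all metabolite gaps filled.
#' @export
impute_metabolites <- function(cohort, max_iter = 10L, n_trees = 100L,
                               seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  kinds <- cohort$features$kind
  nonmet <- kinds != "metabolite"
  for (tp in c("t0", "t1", "t2")) {
    m <- cohort$values[[tp]]
    rows <- if (tp == "t2") cohort$subjects$has_t2 else rep(TRUE, nrow(m))
    if (anyNA(m[rows, nonmet, drop = FALSE]))
      stop("impute_metabolites: missing values present in non-metabolite ",
           "features at ", tp)
  }
  if (!anyNA(cohort$values$t0) && !anyNA(cohort$values$t1) &&
      !anyNA(cohort$values$t2[cohort$subjects$has_t2, , drop = FALSE]))
    return(cohort)

  # stack attended (subject, timepoint) rows into one working matrix
  blocks <- list(t0 = seq_len(nrow(cohort$subjects)),
                 t1 = seq_len(nrow(cohort$subjects)),
                 t2 = which(cohort$subjects$has_t2))
  X <- do.call(rbind, lapply(names(blocks), function(tp)
    cohort$values[[tp]][blocks[[tp]], , drop = FALSE]))
  obs <- !is.na(X)
  met_cols <- which(kinds == "metabolite")
  incomplete <- met_cols[colSums(!obs[, met_cols, drop = FALSE]) > 0]
  if (length(incomplete)) {
    # median initialization
    for (j in incomplete) {
      med <- stats::median(X[obs[, j], j])
      if (is.na(med)) med <- 0  # feature fully missing: no information
      X[!obs[, j], j] <- med
    }
    ord <- incomplete[order(colSums(!obs[, incomplete, drop = FALSE]))]
    prev_change <- Inf
    for (it in seq_len(max_iter)) {
      old <- X
      for (j in ord) {
        miss <- !obs[, j]
        fit <- ranger::ranger(
          x = X[!miss, -j, drop = FALSE], y = X[!miss, j],
          num.trees = n_trees, seed = seed + it * 1009L + j,
          num.threads = 1L)
        X[miss, j] <- stats::predict(
          fit, data = X[miss, -j, drop = FALSE], num.threads = 1L)$predictions
      }
      imp <- !obs[, ord, drop = FALSE]
      change <- sum((X[, ord][imp] - old[, ord][imp])^2) /
        max(sum(X[, ord][imp]^2), .Machine$double.eps)
      if (change < 1e-3 || change >= prev_change) break
      prev_change <- change
    }
  }
  # write imputed cells back
  offset <- 0
  for (tp in names(blocks)) {
    idx <- blocks[[tp]]
    if (length(idx)) {
      cohort$values[[tp]][idx, ] <- X[offset + seq_along(idx), , drop = FALSE]
      offset <- offset + length(idx)
    }
  }
  cohort
}

#' Per-subject changes in the clinical targets
#'
#' One record per (subject, target, horizon) where both the intake (t0) value
#' and the follow-up value are observed: `delta = v_horizon - v_t0`, with the
#' baseline retained. Horizon `6mo` is t1, `1yr` is t2 (follow-up subjects
#' only). The `label` column is `NA` until [binarize_deltas()] is applied.
#'
#' @param cohort A `cohort_table`.
#' @param targets Character vector of target names (default all five).
#' @return A data.frame of class `delta_table` with columns `subject_id`,
#'   `target`, `horizon`, `baseline`, `delta`, `label`.
#' @export
compute_deltas <- function(cohort, targets = clinical_target_names()) {
  stopifnot(inherits(cohort, "cohort_table"),
            all(targets %in% cohort$features$feature_id))
  horizon_tp <- c(`6mo` = "t1", `1yr` = "t2")
  recs <- list()
  for (h in names(horizon_tp)) {
    v0 <- cohort$values$t0[, targets, drop = FALSE]
    vh <- cohort$values[[horizon_tp[[h]]]][, targets, drop = FALSE]
    for (tg in targets) {
      ok <- !is.na(v0[, tg]) & !is.na(vh[, tg])
      if (h == "1yr") ok <- ok & cohort$subjects$has_t2
      if (!any(ok)) next
      recs[[paste(h, tg)]] <- data.frame(
        subject_id = cohort$subjects$subject_id[ok],
        target = tg, horizon = h,
        baseline = v0[ok, tg], delta = vh[ok, tg] - v0[ok, tg],
        label = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(subject_id = character(), target = character(),
               horizon = character(), baseline = numeric(),
               delta = numeric(), label = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Binarize clinical changes at a relative-change threshold
#'
#' Labels a change as the positive class when it moves at least
#' `100*threshold`% in the adverse direction relative to baseline: an
#' increase for HbA1c, glucose, insulin and HOMA-IR, a decrease for eGFR.
#' With `mode = "absolute"` the threshold is instead an absolute change in
#' the variable's own units. Records with non-positive baselines cannot be
#' labeled under the relative rule and are excluded with a warning.
#'
#' @param deltas A `delta_table` from [compute_deltas()].
#' @param threshold Change threshold (default 0.05, i.e. 5% relative).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return The `delta_table` with `label` filled in (1 = adverse change of at
#'   least the threshold, else 0).
#' @export
binarize_deltas <- function(deltas, threshold = 0.05,
                            mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(deltas, "delta_table") || is.data.frame(deltas))
  dir <- target_direction(deltas$target)
  if (mode == "relative") {
    bad <- deltas$baseline <= 0
    if (any(bad)) {
      warning(sum(bad), " record(s) with non-positive baseline excluded ",
              "from binarization")
      deltas <- deltas[!bad, , drop = FALSE]
      dir <- dir[!bad]
    }
    deltas$label <- as.integer(dir * deltas$delta / deltas$baseline >=
                                 threshold)
  } else {
    deltas$label <- as.integer(dir * deltas$delta >= threshold)
  }
  deltas
}

#' Write a delta table as TSV
#' @param deltas A `delta_table`.
#' @param path Output path.
#' @export
write_deltas <- function(deltas, path) {
  utils::write.table(format_numeric_df(as.data.frame(deltas)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
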
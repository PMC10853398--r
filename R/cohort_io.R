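#' Read and write cohort tables
#'
#' The on-disk format is a wide CSV with one row per (subject, timepoint) —
#' columns `subject_id`, `timepoint`, then one column per feature id, with
#' missing values as empty fields — plus a companion registry TSV
#' (`feature_id`, `kind`, `units`) written next to it with suffix
#' `_registry.tsv`. Rows for the 1-year visit (t2) are present only for
#' follow-up subjects. The round trip is lossless, including missing markers
#' and feature kinds.
#'
#' @param cohort A `cohort_table`.
#' @param path Path of the values CSV; the registry path is derived from it.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  rows <- list()
  for (tp in c("t0", "t1", "t2")) {
    m <- cohort$values[[tp]]
    keep <- if (tp == "t2") cohort$subjects$has_t2 else
      rep(TRUE, nrow(cohort$subjects))
    if (!any(keep)) next
    df <- as.data.frame(m[keep, , drop = FALSE])
    rows[[tp]] <- cbind(
      data.frame(subject_id = cohort$subjects$subject_id[keep],
                 timepoint = tp, stringsAsFactors = FALSE),
      df)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {  # zero subjects: header-only file
    out <- data.frame(matrix(nrow = 0, ncol = 2 + nrow(cohort$features)))
    names(out) <- c("subject_id", "timepoint", cohort$features$feature_id)
  }
  utils::write.csv(format_numeric_df(out), path, row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.table(cohort$features, registry_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

registry_path <- function(path)
  paste0(sub("\\.csv$", "", path), "_registry.tsv")

# fixed-precision text rendering so round trips and file hashes are stable
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- df[[j]]
      df[[j]] <- ifelse(is.na(x), NA, sprintf("%.17g", x))
    }
  }
  df
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  reg_path <- registry_path(path)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (!file.exists(reg_path)) stop("registry file not found: ", reg_path)
  features <- utils::read.delim(reg_path, stringsAsFactors = FALSE,
                                colClasses = "character")
  if (!identical(names(features), c("feature_id", "kind", "units")))
    stop("parse error in ", reg_path, ": expected columns ",
         "feature_id, kind, units")
  bad <- which(!(features$kind %in%
                   c("demographic", "clinical", "protein", "metabolite")))
  if (length(bad))
    stop("parse error in ", reg_path, " line ", bad[1] + 1,
         ": unknown feature kind '", features$kind[bad[1]], "'")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  expected <- c("subject_id", "timepoint", features$feature_id)
  if (!identical(names(raw), expected))
    stop("parse error in ", path, ": header does not match registry")
  bad_tp <- which(!(raw$timepoint %in% c("t0", "t1", "t2")))
  if (length(bad_tp))
    stop("parse error in ", path, " line ", bad_tp[1] + 1,
         " column 2: unknown timepoint '", raw$timepoint[bad_tp[1]], "'")

  subject_id <- unique(raw$subject_id[raw$timepoint == "t0"])
  if (!all(raw$subject_id %in% subject_id))
    stop("parse error in ", path, ": subject without a t0 record: ",
         setdiff(raw$subject_id, subject_id)[1])
  n <- length(subject_id)
  p <- nrow(features)
  vals <- lapply(c(t0 = "t0", t1 = "t1", t2 = "t2"), function(tp) {
    m <- matrix(NA_real_, n, p,
                dimnames = list(subject_id, features$feature_id))
    idx <- which(raw$timepoint == tp)
    for (i in idx) {
      cells <- as.character(raw[i, -(1:2)])
      num <- suppressWarnings(as.numeric(cells))
      bad_cell <- which(!is.na(cells) & cells != "" & is.na(num))
      if (length(bad_cell))
        stop("parse error in ", path, " line ", i + 1, " column ",
             bad_cell[1] + 2, ": not numeric: '", cells[bad_cell[1]], "'")
      num[!is.na(cells) & cells == ""] <- NA_real_
      m[raw$subject_id[i], ] <- num
    }
    m
  })
  t0m <- vals$t0
  has_t2 <- subject_id %in% raw$subject_id[raw$timepoint == "t2"]
  subjects <- data.frame(
    subject_id = subject_id,
    age = if ("age" %in% colnames(t0m)) t0m[, "age"] else NA_real_,
    sex = if ("sex" %in% colnames(t0m)) t0m[, "sex"] else NA_real_,
    bmi = if ("BMI" %in% colnames(t0m)) t0m[, "BMI"] else NA_real_,
    has_t2 = has_t2, stringsAsFactors = FALSE)
  new_cohort_table(subjects, features, vals)
}
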
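#' Clinical targets of the trajectory models
#'
#' The five clinical variables whose 6-month and 1-year changes the package
#' predicts: glycated hemoglobin (HbA1c, %), fasting glucose (mg/dL), fasting
#' insulin (uIU/mL), the HOMA-IR insulin-resistance index (unitless, derived
#' as glucose x insulin / 405) and the estimated glomerular filtration rate
#' (eGFR, mL/min/1.73m2).
#'
#' For HbA1c, glucose, insulin and HOMA-IR an *increase* is the positive
#' (adverse) class when changes are binarized; for eGFR a *decrease* is,
#' because falling kidney function is the adverse event.
#'
#' @return A data.frame with columns `target`, `units` and `direction`
#'   (+1 if an increase is the positive class, -1 for eGFR).
#' @export
#' @examples
#' clinical_targets()
clinical_targets <- function() {
  data.frame(
    target = c("HbA1c", "glucose", "insulin", "HOMA_IR", "eGFR"),
    units = c("%", "mg/dL", "uIU/mL", "unitless", "mL/min/1.73m2"),
    direction = c(1L, 1L, 1L, 1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' @rdname clinical_targets
#' @export
clinical_target_names <- function() clinical_targets()$target

# direction lookup used by binarize_deltas()
target_direction <- function(target) {
  tt <- clinical_targets()
  d <- tt$direction[match(target, tt$target)]
  if (anyNA(d)) stop("unknown clinical target: ",
                     paste(target[is.na(d)], collapse = ", "))
  d
}

# HOMA-IR convention: glucose in mg/dL, insulin in uIU/mL
homa_ir <- function(glucose, insulin) glucose * insulin / 405
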
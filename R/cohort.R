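#' Assemble the analysis cohort from raw admissions
#'
#' Applies the audit exclusions: maternity admissions, stays shorter than
#' 24 hours, and maintenance-dialysis patients (no effective native renal
#' function).  CKD stage 4/5 patients not on dialysis are retained.
#'
#' @param admissions Admission data frame; must contain `admission_id`,
#'   `admission_time`, `discharge_time` and (optionally) logical columns
#'   `maternity` and `maintenance_dialysis`.
#' @return List with `cohort` (included admissions, with an `los_days`
#'   column, whole days by floor) and `exclusions` (data frame of
#'   `admission_id`, `reason`).
#' @export
assemble_cohort <- function(admissions) {
  stopifnot(is.data.frame(admissions))
  if (nrow(admissions) == 0L) {
    return(list(cohort = admissions,
                exclusions = data.frame(admission_id = character(),
                                        reason = character())))
  }
  req <- c("admission_id", "admission_time", "discharge_time")
  missing_cols <- setdiff(req, names(admissions))
  if (length(missing_cols))
    stop("admissions lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(admissions$admission_id))
    stop("duplicate admission_id values", call. = FALSE)

  los_h <- as.numeric(difftime(admissions$discharge_time,
                               admissions$admission_time, units = "hours"))
  if (any(los_h < 0)) stop("discharge before admission", call. = FALSE)

  reason <- rep(NA_character_, nrow(admissions))
  if ("maternity" %in% names(admissions))
    reason[is.na(reason) & admissions$maternity %in% TRUE] <- "maternity"
  reason[is.na(reason) & los_h < 24] <- "short-stay"
  if ("maintenance_dialysis" %in% names(admissions))
    reason[is.na(reason) & admissions$maintenance_dialysis %in% TRUE] <-
      "maintenance-dialysis"

  cohort <- admissions[is.na(reason), , drop = FALSE]
  cohort$los_days <- floor(los_h[is.na(reason)] / 24)
  list(
    cohort = cohort,
    exclusions = data.frame(
      admission_id = admissions$admission_id[!is.na(reason)],
      reason = reason[!is.na(reason)],
      stringsAsFactors = FALSE
    )
  )
}

#' Audit sepsis flag from laboratory and observation components
#'
#' Sepsis is recorded when at least two of three indicators hold: white
#' cell count < 4 or > 12 x 10^9/L, C-reactive protein > 50 mg/L, and
#' pyrexia (temperature > 38.0 C).  A missing component counts as
#' criterion not met.
#'
#' @param wcc White cell count, 10^9/L (may be `NA`).
#' @param crp C-reactive protein, mg/L (may be `NA`).
#' @param max_temp Maximum recorded temperature, degrees C (may be `NA`).
#' @return Logical vector.
#' @export
sepsis_flag <- function(wcc, crp, max_temp) {
  wcc_crit <- !is.na(wcc) & (wcc < 4 | wcc > 12)
  crp_crit <- !is.na(crp) & crp > 50
  temp_crit <- !is.na(max_temp) & max_temp > 38.0
  (wcc_crit + crp_crit + temp_crit) >= 2
}

#' Flag admissions where an indicated repeat creatinine was never taken
#'
#' An admission eGFR below 60 mL/min mandates repeat testing unless a
#' documented baseline within the prior six months shows no change.
#' Returns `TRUE` when only a single creatinine exists despite the
#' indication.
#'
#' @param series In-hospital [lab_series()] for the admission.
#' @param admission_egfr eGFR of the admission sample, mL/min/1.73 m^2.
#' @param baseline A [baseline_function()] or `NULL`.
#' @param tolerance Relative change from baseline regarded as "no change"
#'   (default 10 per cent).
#' @return Logical scalar.
#' @export
repeat_testing_flag <- function(series, admission_egfr, baseline = NULL,
                                tolerance = 0.1) {
  series <- as_lab_series(series)
  if (nrow(series) != 1L) return(FALSE)
  if (is.na(admission_egfr) || admission_egfr >= 60) return(FALSE)
  if (!is.null(baseline) && baseline$source == "measured-prior") {
    unchanged <- abs(series$creatinine[1] - baseline$creatinine) <=
      tolerance * baseline$creatinine
    if (unchanged) return(FALSE)
  }
  TRUE
}
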
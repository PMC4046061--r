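#' Four-variable MDRD estimated glomerular filtration rate
#'
#' Computes the IDMS-traceable four-variable MDRD eGFR from serum
#' creatinine, age, sex and ethnicity:
#' \deqn{\mathrm{eGFR} = 175 \times (\mathrm{SCr}/88.4)^{-1.154} \times
#'   \mathrm{age}^{-0.203} \times 0.742^{[\mathrm{female}]} \times
#'   1.212^{[\mathrm{black}]}}
#' with creatinine in umol/L (the division by 88.4 converts to mg/dL).
#'
#' @param creatinine Serum creatinine in umol/L (positive).
#' @param age Age in years (>= 18; the MDRD equation is not validated in
#'   children).
#' @param sex `"F"` or `"M"` (recycled).
#' @param black Logical; apply the 1.212 ethnicity factor.
#' @return eGFR in mL/min/1.73 m^2, same length as the inputs.
#' @examples
#' mdrd_egfr(88.4, 50, "M")   # 79.1
#' mdrd_egfr(88.4, 50, "F")   # 58.7
#' @export
mdrd_egfr <- function(creatinine, age, sex, black = FALSE) {
  n <- max(length(creatinine), length(age), length(sex), length(black))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  black <- rep_len(black, n)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("'creatinine' must be positive and finite", call. = FALSE)
  if (any(!is.finite(age)) || any(age < 18))
    stop("'age' must be >= 18 years for the adult MDRD equation", call. = FALSE)
  if (!all(sex %in% c("F", "M")))
    stop("'sex' must be \"F\" or \"M\"", call. = FALSE)
  175 * (creatinine / 88.4)^(-1.154) * age^(-0.203) *
    ifelse(sex == "F", 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Baseline renal function for an admission
#'
#' Container describing the reference renal function against which
#' creatinine rises and eGFR falls are judged.
#'
#' @param creatinine Baseline serum creatinine, umol/L.
#' @param egfr Baseline eGFR, mL/min/1.73 m^2.
#' @param source One of `"measured-prior"` (lowest laboratory value in the
#'   six months before admission), `"admission"` (the admission sample is
#'   the best available reference) or `"assumed-normal"` (no history; eGFR
#'   75 with sex-specific creatinine 60 F / 80 M).
#' @param reference_time `POSIXct` time of the reference measurement, or
#'   `NA` when unknown (assumed-normal baselines).
#' @return An object of class `"baseline_function"`.
#' @export
baseline_function <- function(creatinine, egfr, source, reference_time = as.POSIXct(NA)) {
  source <- match.arg(source, c("measured-prior", "admission", "assumed-normal"))
  stopifnot(is.numeric(creatinine), length(creatinine) == 1L, creatinine > 0,
            is.numeric(egfr), length(egfr) == 1L, egfr > 0)
  structure(
    list(creatinine = creatinine, egfr = egfr, source = source,
         reference_time = as.POSIXct(reference_time)),
    class = "baseline_function"
  )
}

#' @export
print.baseline_function <- function(x, ...) {
  cat(sprintf("Baseline renal function: creatinine %.1f umol/L, eGFR %.1f mL/min/1.73m2\n",
              x$creatinine, x$egfr))
  cat(sprintf("  source: %s; reference time: %s\n", x$source,
              if (is.na(x$reference_time)) "unknown" else format(x$reference_time)))
  invisible(x)
}

# Sex-specific assumed-normal creatinine (midpoint of laboratory normal
# range): 60 umol/L female, 80 umol/L male; paired with an assumed eGFR of
# 75 mL/min/1.73 m^2.
assumed_normal_creatinine <- function(sex) {
  ifelse(as.character(sex) == "F", 60, 80)
}

#' Determine an admission's baseline renal function
#'
#' Applies the audit's baseline rules.  When prior creatinine results exist
#' within the six months (183 days) before admission, the baseline is the
#' lowest of those values; if the admission sample is lower still, the
#' admission value is taken as the reference ("the better result").  When
#' no prior result exists and there is no history of renal impairment, a
#' normal baseline is assumed: eGFR 75 mL/min with creatinine 60 (F) / 80
#' (M) umol/L.  When no prior result exists but renal impairment is
#' documented, the admission value itself is the reference.
#'
#' @param prior Data frame of prior measurements with columns `timestamp`
#'   (`POSIXct`) and `creatinine` (umol/L); may have zero rows.  Rows
#'   outside the 183-day window before `admission_time` are ignored.
#' @param admission_value Serum creatinine of the admission sample
#'   (umol/L), or `NA` if never measured.
#' @param admission_time `POSIXct` admission time.
#' @param known_renal_impairment Logical; documented CKD / renal
#'   impairment history.
#' @param sex,age,black Demographics used to compute the baseline eGFR.
#' @return A [baseline_function()].
#' @export
determine_baseline <- function(prior, admission_value, admission_time,
                               known_renal_impairment = FALSE,
                               sex = "M", age = 60, black = FALSE) {
  if (is.null(prior) || nrow(prior) == 0L) {
    prior <- data.frame(timestamp = as.POSIXct(character()), creatinine = numeric())
  }
  stopifnot(all(c("timestamp", "creatinine") %in% names(prior)))
  window_start <- admission_time - 183 * 86400
  keep <- prior$timestamp >= window_start & prior$timestamp <= admission_time
  prior <- prior[keep, , drop = FALSE]

  if (nrow(prior) == 0L && (is.na(admission_value) || length(admission_value) == 0L)) {
    stop("unclassifiable: no prior creatinine and no admission creatinine",
         call. = FALSE)
  }

  if (nrow(prior) > 0L) {
    i <- which.min(prior$creatinine)
    prior_low <- prior$creatinine[i]
    if (!is.na(admission_value) && admission_value < prior_low) {
      return(baseline_function(admission_value,
                               mdrd_egfr(admission_value, age, sex, black),
                               "admission", admission_time))
    }
    return(baseline_function(prior_low,
                             mdrd_egfr(prior_low, age, sex, black),
                             "measured-prior", prior$timestamp[i]))
  }

  if (known_renal_impairment) {
    return(baseline_function(admission_value,
                             mdrd_egfr(admission_value, age, sex, black),
                             "admission", admission_time))
  }
  baseline_function(assumed_normal_creatinine(sex), 75, "assumed-normal")
}
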
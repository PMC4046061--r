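#' Timestamped serum-creatinine series for one admission
#'
#' Validates and orders a set of creatinine measurements.  Timestamps must
#' be strictly increasing and values strictly positive.
#'
#' @param timestamp `POSIXct` vector (minute resolution is sufficient).
#' @param creatinine Serum creatinine values, umol/L.
#' @param setting `"pre-admission"` or `"in-hospital"` per measurement.
#' @return A data frame of class `"lab_series"` with columns `timestamp`,
#'   `creatinine`, `setting`, ordered by time.
#' @export
lab_series <- function(timestamp, creatinine, setting = "in-hospital") {
  timestamp <- as.POSIXct(timestamp)
  if (length(timestamp) != length(creatinine))
    stop("'timestamp' and 'creatinine' lengths differ", call. = FALSE)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("creatinine values must be positive", call. = FALSE)
  setting <- rep_len(as.character(setting), length(timestamp))
  if (!all(setting %in% c("pre-admission", "in-hospital")))
    stop("'setting' must be \"pre-admission\" or \"in-hospital\"", call. = FALSE)
  if (is.unsorted(timestamp, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  structure(
    data.frame(timestamp = timestamp, creatinine = creatinine, setting = setting),
    class = c("lab_series", "data.frame")
  )
}

# Coerce a plain data.frame (e.g. a labs-CSV subset) to a lab_series,
# sorting by time first.
as_lab_series <- function(x) {
  if (inherits(x, "lab_series")) return(x)
  o <- order(x$timestamp)
  lab_series(x$timestamp[o], x$creatinine[o],
             if ("setting" %in% names(x)) x$setting[o] else "in-hospital")
}

#' Recorded anuria / oliguria interval
#'
#' @param start,end `POSIXct` interval bounds, `end > start`.
#' @param kind `"anuria"` (no urine output) or `"oliguria"`
#'   (< 400 mL/day).  Only anuria participates in staging (for > 12 h);
#'   oliguria is descriptive.
#' @return One-row data frame with columns `start`, `end`, `kind`.
#' @export
anuria_interval <- function(start, end, kind = "anuria") {
  start <- as.POSIXct(start); end <- as.POSIXct(end)
  kind <- match.arg(kind, c("anuria", "oliguria"))
  if (!(end > start)) stop("'end' must be after 'start'", call. = FALSE)
  data.frame(start = start, end = end, kind = kind)
}

# Longest recorded anuria duration in hours.  Accepts a numeric number of
# hours (already summarised), a data frame of anuria_interval() rows, or
# NULL.
max_anuria_hours <- function(anuria) {
  if (is.null(anuria) || length(anuria) == 0L) return(0)
  if (is.numeric(anuria)) return(max(0, anuria, na.rm = TRUE))
  stopifnot(is.data.frame(anuria))
  an <- anuria[anuria$kind == "anuria", , drop = FALSE]
  if (nrow(an) == 0L) return(0)
  max(as.numeric(difftime(an$end, an$start, units = "hours")))
}
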
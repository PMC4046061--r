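# Shorthand builders used across the unit tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

T0 <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC")

series_at <- function(hours, values, setting = "in-hospital") {
  lab_series(T0 + hours * 3600, values, setting)
}

baseline_at <- function(creatinine, egfr = NULL, source = "measured-prior",
                        hours_before = 30 * 24, age = 60, sex = "M") {
  if (is.null(egfr)) egfr <- mdrd_egfr(creatinine, age, sex)
  rt <- if (source == "assumed-normal") as.POSIXct(NA) else T0 - hours_before * 3600
  baseline_function(creatinine, egfr, source, rt)
}

demo_admission <- function(age = 60, sex = "M", ...) {
  c(list(age = age, sex = sex), list(...))
}
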
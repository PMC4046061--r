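#' @name staging
#' @title Creatinine-based AKI staging (RIFLE, AKIN, AKIB)
#'
#' @description
#' The three staging systems are evaluated on an irregularly sampled
#' creatinine series against a rolling reference ("rolling nadir"): for a
#' measurement at time \eqn{t} the reference is the minimum eligible value
#' in the half-open look-back window \eqn{(t - w, t]}, where eligible
#' values are earlier in-window measurements plus the baseline when its
#' reference time falls in the window, when the baseline is assumed-normal
#' (its time is unknown by construction), or when the pre-admission
#' assumption applies to the admission sample.
#'
#' All inequalities are strict, as the criteria are written: a rise of
#' exactly 26 umol/L or a ratio of exactly 1.5 does not trigger.
#'
#' * RIFLE (window 7 days): Risk / Injury / Failure at creatinine
#'   > 1.5x / > 2x / > 3x the reference, or eGFR decrease > 25 / > 50 /
#'   > 75 per cent; anuria > 12 h is Failure.
#' * AKIN (window 48 h): stage 1 at > 1.5x or a rise > 26 umol/L; stage 2
#'   at > 2x; stage 3 at > 3x, a rise > 44 umol/L from a reference
#'   > 300 umol/L, any renal replacement therapy, or anuria > 12 h.
#' * AKIB (absolute rises only): stage 1 at > 26 umol/L / 24 h or
#'   > 44 / 48 h; stage 2 at > 44 / 24 h or > 88 / 48 h; stage 3 at
#'   > 88 / 24 h or > 132 / 48 h.  The baseline participates only as an
#'   ordinary measurement when its time is known.
NULL

HOUR <- 3600

# Rolling-window reference statistics on one series.
# t: numeric times (seconds), sorted; v: creatinine; w: window in seconds.
# b/bt: baseline value and time (bt NA if unknown); b_always: baseline
# eligible at every point (assumed-normal / unknown-time baselines);
# first_elig: baseline additionally eligible at the first measurement (the
# pre-admission assumption).
window_stats <- function(t, v, w, b = NA_real_, bt = NA_real_,
                         b_always = FALSE, first_elig = FALSE) {
  n <- length(t)
  ratio <- rise <- numeric(n)
  rise_hi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    refs <- v[t > t[i] - w & t <= t[i]]
    elig <- !is.na(b) &&
      (b_always || (first_elig && i == 1L) ||
         (!is.na(bt) && bt > t[i] - w && bt <= t[i]))
    if (elig) refs <- c(refs, b)
    r <- min(refs)
    ratio[i] <- v[i] / r
    rise[i] <- v[i] - r
    hi <- refs[refs > 300]
    if (length(hi)) rise_hi[i] <- v[i] - min(hi)
  }
  list(ratio = ratio, rise = rise, rise_hi = rise_hi)
}

# eGFR percentage decline against the rolling *maximum* eligible eGFR.
egfr_decline <- function(t, e, w, be = NA_real_, bt = NA_real_,
                         b_always = FALSE, first_elig = FALSE) {
  n <- length(t)
  dec <- numeric(n)
  for (i in seq_len(n)) {
    refs <- e[t > t[i] - w & t <= t[i]]
    elig <- !is.na(be) &&
      (b_always || (first_elig && i == 1L) ||
         (!is.na(bt) && bt > t[i] - w && bt <= t[i]))
    if (elig) refs <- c(refs, be)
    dec[i] <- 100 * (1 - e[i] / max(refs))
  }
  dec
}

#' Rolling-window reference, ratio and rise on an irregular series
#'
#' Operationalises "over 48 hours" / "over 7 days" on an irregularly
#' sampled series: for each measurement at time \eqn{t} the reference is
#' the minimum eligible value in \eqn{(t - w, t]} — earlier in-window
#' measurements plus the baseline when eligible (reference time in the
#' window, assumed-normal source, or `baseline_always = TRUE`).
#'
#' @param series A [lab_series()].
#' @param baseline A [baseline_function()] or `NULL`.
#' @param window Look-back window in hours.
#' @param baseline_always Force baseline eligibility at every measurement
#'   (the pre-admission assumption applied globally).
#' @return List with `per_measurement` (data frame: `timestamp`, `value`,
#'   `reference`, `ratio`, `rise`), `max_ratio` and `max_rise`.
#' @export
windowed_extremes <- function(series, baseline = NULL, window = 48,
                              baseline_always = FALSE) {
  s <- prep_series(series)
  if (is.null(baseline)) {
    bp <- list(b = NA_real_, bt = NA_real_, b_always = FALSE)
  } else {
    bp <- baseline_params(baseline)
  }
  ws <- window_stats(s$t, s$v, window * HOUR, bp$b, bp$bt,
                     b_always = bp$b_always || baseline_always)
  list(
    per_measurement = data.frame(
      timestamp = s$ts, value = s$v,
      reference = s$v / ws$ratio, ratio = ws$ratio, rise = ws$rise
    ),
    max_ratio = max(ws$ratio), max_rise = max(ws$rise)
  )
}

aki_episode <- function(system, stage, trigger = NA_character_,
                        trigger_time = as.POSIXct(NA), timing = NA_character_,
                        admission_id = NA_character_) {
  labels <- list(
    RIFLE = c("none", "Risk", "Injury", "Failure"),
    AKIN = c("none", "1", "2", "3"),
    AKIB = c("none", "1", "2", "3")
  )
  data.frame(
    admission_id = admission_id, system = system, stage = stage,
    stage_label = labels[[system]][stage + 1L],
    trigger = trigger, trigger_time = as.POSIXct(trigger_time),
    timing = timing, stringsAsFactors = FALSE
  )
}

# Shared preparation: validate series, pull numeric times/values, baseline
# eligibility parameters.
prep_series <- function(series) {
  series <- as_lab_series(series)
  if (nrow(series) == 0L)
    stop("unclassifiable: series has no measurements", call. = FALSE)
  list(t = as.numeric(series$timestamp), v = series$creatinine,
       ts = series$timestamp)
}

baseline_params <- function(baseline) {
  if (is.null(baseline)) stop("unclassifiable: baseline missing", call. = FALSE)
  stopifnot(inherits(baseline, "baseline_function"))
  list(b = baseline$creatinine, be = baseline$egfr,
       bt = if (is.na(baseline$reference_time)) NA_real_
            else as.numeric(baseline$reference_time),
       b_always = baseline$source == "assumed-normal" ||
         is.na(baseline$reference_time))
}

# First time (index) at which per-measurement stage vector reaches `stage`.
first_hit <- function(stage_vec, stage) {
  i <- which(stage_vec >= stage)
  if (length(i)) i[1] else NA_integer_
}

#' Stage one admission under the RIFLE creatinine/eGFR criteria
#'
#' @param series A [lab_series()] of in-hospital measurements.
#' @param baseline A [baseline_function()].
#' @param anuria Recorded anuria: hours (numeric), a data frame of
#'   [anuria_interval()] rows, or `NULL`.
#' @param egfr Optional per-measurement eGFR vector aligned with `series`;
#'   when `NULL` the eGFR-decline rules are not evaluated.
#' @param assume_recent_baseline Treat the baseline as in-window at the
#'   first measurement (the pre-admission assumption: an unexplained rise
#'   present on admission is taken to have occurred within 7 days).
#' @return One-row episode data frame (`system`, `stage`, `stage_label`,
#'   `trigger`, `trigger_time`, `timing`).
#' @export
stage_rifle <- function(series, baseline, anuria = NULL, egfr = NULL,
                        assume_recent_baseline = TRUE) {
  s <- prep_series(series); bp <- baseline_params(baseline)
  w <- 7 * 24 * HOUR
  ws <- window_stats(s$t, s$v, w, bp$b, bp$bt, bp$b_always,
                     first_elig = assume_recent_baseline)
  ratio_stage <- (ws$ratio > 1.5) + (ws$ratio > 2) + (ws$ratio > 3)
  if (!is.null(egfr)) {
    stopifnot(length(egfr) == length(s$v))
    dec <- egfr_decline(s$t, egfr, w, bp$be, bp$bt, bp$b_always,
                        first_elig = assume_recent_baseline)
    egfr_stage <- (dec > 25) + (dec > 50) + (dec > 75)
  } else {
    egfr_stage <- rep(0L, length(s$v))
  }
  anuria_stage <- if (max_anuria_hours(anuria) > 12) 3L else 0L
  stage <- max(ratio_stage, egfr_stage, anuria_stage)
  if (stage == 0L) return(aki_episode("RIFLE", 0L, timing = "none"))
  i_r <- first_hit(ratio_stage, stage); i_e <- first_hit(egfr_stage, stage)
  if (!is.na(i_r) && (is.na(i_e) || i_r <= i_e)) {
    aki_episode("RIFLE", stage, "ratio", s$ts[i_r])
  } else if (!is.na(i_e)) {
    aki_episode("RIFLE", stage, "egfr-decline", s$ts[i_e])
  } else {
    aki_episode("RIFLE", stage, "anuria")
  }
}

#' Stage one admission under the AKIN criteria
#'
#' @inheritParams stage_rifle
#' @param any_rrt Logical; any renal replacement therapy during the
#'   admission (AKIN stage 3).
#' @param assume_recent_baseline Pre-admission assumption: the rise from
#'   baseline to the admission sample is taken to be within 48 h.
#' @return One-row episode data frame.
#' @export
stage_akin <- function(series, baseline, anuria = NULL, any_rrt = FALSE,
                       assume_recent_baseline = TRUE) {
  s <- prep_series(series); bp <- baseline_params(baseline)
  ws <- window_stats(s$t, s$v, 48 * HOUR, bp$b, bp$bt, bp$b_always,
                     first_elig = assume_recent_baseline)
  meas_stage <- pmax(
    (ws$ratio > 1.5) + (ws$ratio > 2) + (ws$ratio > 3),
    ifelse(ws$rise > 26, 1L, 0L),
    ifelse(!is.na(ws$rise_hi) & ws$rise_hi > 44, 3L, 0L)
  )
  special <- max(if (any_rrt) 3L else 0L,
                 if (max_anuria_hours(anuria) > 12) 3L else 0L)
  stage <- max(meas_stage, special)
  if (stage == 0L) return(aki_episode("AKIN", 0L, timing = "none"))
  i <- first_hit(meas_stage, stage)
  if (!is.na(i)) {
    ratio_hit <- (ws$ratio[i] > 1.5) + (ws$ratio[i] > 2) + (ws$ratio[i] > 3) >= stage
    aki_episode("AKIN", stage, if (ratio_hit) "ratio" else "absolute-rise", s$ts[i])
  } else if (any_rrt) {
    aki_episode("AKIN", stage, "rrt")
  } else {
    aki_episode("AKIN", stage, "anuria")
  }
}

#' Stage one admission under the AKIB absolute-rise criteria
#'
#' @inheritParams stage_rifle
#' @param baseline Optional; used only as an extra measurement when its
#'   reference time is known (`measured-prior` source).  AKIB has no
#'   urine-output, RRT or assumed-baseline rules.
#' @return One-row episode data frame.
#' @export
stage_akib <- function(series, baseline = NULL) {
  s <- prep_series(series)
  t <- s$t; v <- v0 <- s$v; ts <- s$ts
  if (!is.null(baseline) && inherits(baseline, "baseline_function") &&
      baseline$source == "measured-prior" && !is.na(baseline$reference_time)) {
    bt <- as.numeric(baseline$reference_time)
    if (bt < t[1]) {
      t <- c(bt, t); v <- c(baseline$creatinine, v)
      ts <- c(baseline$reference_time, ts)
    }
  }
  r24 <- window_stats(t, v, 24 * HOUR)$rise
  r48 <- window_stats(t, v, 48 * HOUR)$rise
  meas_stage <- pmax((r24 > 26) + (r24 > 44) + (r24 > 88),
                     (r48 > 44) + (r48 > 88) + (r48 > 132))
  stage <- max(meas_stage, 0L)
  if (stage == 0L) return(aki_episode("AKIB", 0L, timing = "none"))
  i <- first_hit(meas_stage, stage)
  aki_episode("AKIB", stage, "absolute-rise", ts[i])
}

#' Classify an admission under all three staging systems
#'
#' Runs RIFLE, AKIN and AKIB on the in-hospital series, recording for each
#' system the single most severe stage reached at any time during the
#' admission, its triggering rule and time, and whether the criterion was
#' already met by the admission sample against the baseline
#' (`pre-admission`) or first met later (`post-admission`).  For the
#' pre-admission comparison the rise from an old or unknown-time baseline
#' is assumed to lie within the system's window (7 days for RIFLE, 48 h
#' for AKIN); AKIB carries no such assumption.
#'
#' @param admission List or one-row data frame with at least `age`, `sex`,
#'   and optionally `black`, `acute_rrt`, `anuria_hours`, `admission_id`.
#' @param labs A [lab_series()]; only `in-hospital` rows are staged
#'   (pre-admission rows belong to baseline determination).
#' @param baseline A [baseline_function()].
#' @param systems Character subset of `c("RIFLE", "AKIN", "AKIB")`.
#' @return Data frame with one row per requested system.
#' @export
classify_admission <- function(admission, labs, baseline,
                               systems = c("RIFLE", "AKIN", "AKIB")) {
  systems <- match.arg(systems, several.ok = TRUE)
  labs <- as_lab_series(labs)
  inpt <- labs[labs$setting == "in-hospital", , drop = FALSE]
  if (nrow(inpt) == 0L)
    stop("unclassifiable: admission has no in-hospital creatinine", call. = FALSE)
  series <- lab_series(inpt$timestamp, inpt$creatinine, "in-hospital")
  adm1 <- series[1L, , drop = FALSE]

  a <- as.list(admission)
  aid <- if (!is.null(a$admission_id)) as.character(a$admission_id) else NA_character_
  black <- isTRUE(a$black) || identical(a$ethnicity, "black")
  rrt <- isTRUE(a$acute_rrt)
  anuria <- if (!is.null(a$anuria_hours)) a$anuria_hours else a$anuria
  egfr <- if (!is.null(a$age) && !is.null(a$sex))
    mdrd_egfr(series$creatinine, a$age, a$sex, black) else NULL

  out <- lapply(systems, function(sys) {
    full <- switch(sys,
      RIFLE = stage_rifle(series, baseline, anuria, egfr),
      AKIN = stage_akin(series, baseline, anuria, any_rrt = rrt),
      AKIB = stage_akib(series, baseline))
    if (full$stage == 0L) {
      full$timing <- "none"
    } else {
      pre <- switch(sys,
        RIFLE = stage_rifle(adm1, baseline, anuria = NULL,
                            egfr = if (is.null(egfr)) NULL else egfr[1L]),
        AKIN = stage_akin(adm1, baseline, anuria = NULL, any_rrt = FALSE),
        AKIB = stage_akib(adm1, baseline))
      full$timing <- if (pre$stage >= 1L) "pre-admission" else "post-admission"
    }
    full$admission_id <- aid
    full
  })
  do.call(rbind, out)
}
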
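#' Reference configuration for the synthetic admission cohort
#'
#' Returns the default [cohort_config()], calibrated to the marginal rates
#' of an unselected emergency-admission cohort: 25.4 per cent AKI
#' incidence skewed to stage 1, 45.7 per cent of patients with a known
#' prior-six-month baseline, comorbidity-linked AKI risk (known CKD,
#' sepsis, diuretics, age), median length of stay 4 days without AKI
#' versus about 10 with, mortality 3.3 versus 11.4 per cent, and
#' critical-care use 1.7 versus 8.1 per cent.
#'
#' @param n_admissions Number of raw admissions to draw (before audit
#'   exclusions).
#' @param seed RNG seed stored in the config; `generate_cohort()` seeds
#'   from it so the same (config, seed) always yields an identical cohort.
#' @param ... Overrides for any [cohort_config()] field.
#' @return A `cohort_config`.
#' @export
reference_config <- function(n_admissions = 745, seed = 1, ...) {
  cohort_config(n_admissions = n_admissions, seed = seed, ...)
}

#' Synthetic-cohort configuration
#'
#' All probabilities are per admission; log-odds act on the logistic AKI
#' risk model whose intercept is solved numerically so that the mean risk
#' equals `target_incidence`.
#'
#' @param n_admissions,seed Size and seed.
#' @param target_incidence Marginal probability of AKI (any criterion) in
#'   the analysed cohort.
#' @param stage_mix Probabilities of stages 1-3 given AKI (sums to 1).
#' @param system_weights Sampling weights for the criterion set a
#'   synthetic AKI episode is written against.
#' @param frac_pre_admission Probability an AKI episode is already present
#'   in the admission sample.
#' @param fraction_known_baseline Probability a prior-six-month creatinine
#'   exists.
#' @param prevalence Named list of comorbidity/exposure prevalences.
#' @param log_odds Named list of AKI log-odds: `ckd`, `sepsis`,
#'   `diuretic`, and `age_per_year` (slope per year of age).
#' @param los_meanlog_none,los_meanlog_stage,los_sdlog Log-normal LOS
#'   parameters (days): one meanlog without AKI, one per stage with.
#' @param mortality_none,mortality_stage Death probabilities.
#' @param critical_care_none,critical_care_stage Critical-care admission
#'   probabilities.
#' @param rrt_stage3 Probability of acute RRT given stage 3.
#' @param anuria_stage3 Probability of recorded anuria > 12 h given stage 3.
#' @param maternity_rate,short_stay_rate,maintenance_dialysis_rate
#'   Prevalence of admissions the audit excludes.
#' @param single_test_rate Fraction of non-AKI admissions with only one
#'   creatinine measurement.
#' @param sampling_rate In-hospital creatinine measurements per day.
#' @param noise_sd Log-scale SD of multiplicative measurement noise.
#' @param age_mean,age_sd,male_frac Demographics.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_admissions = 745,
                          seed = 1,
                          target_incidence = 0.254,
                          stage_mix = c(0.68, 0.20, 0.12),
                          system_weights = c(RIFLE = 0.25, AKIN = 0.55, AKIB = 0.20),
                          frac_pre_admission = 0.573,
                          fraction_known_baseline = 0.457,
                          prevalence = list(diabetes = 0.20, hypertension = 0.35,
                                            known_ckd = 0.08, ckd45 = 0.029,
                                            nsaid = 0.08, acei_arb = 0.20,
                                            diuretic = 0.25, contrast = 0.10,
                                            sepsis = 0.15, oliguria = 0.06),
                          log_odds = list(ckd = log(4.02), sepsis = log(7.24),
                                          diuretic = log(1.87),
                                          age_per_year = log(1.02)),
                          los_meanlog_none = log(4),
                          los_meanlog_stage = log(c(8, 12, 16)),
                          los_sdlog = 0.6,
                          mortality_none = 0.033,
                          mortality_stage = c(0.103, 0.147, 0.15),
                          critical_care_none = 0.017,
                          critical_care_stage = c(0.043, 0.118, 0.238),
                          rrt_stage3 = 0.33,
                          anuria_stage3 = 0.3,
                          maternity_rate = 0.012,
                          short_stay_rate = 0.008,
                          maintenance_dialysis_rate = 0.023,
                          single_test_rate = 0.28,
                          sampling_rate = 1,
                          noise_sd = 0.04,
                          age_mean = 62, age_sd = 20, male_frac = 0.546) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$target_incidence, cfg$frac_pre_admission,
             cfg$fraction_known_baseline, unlist(cfg$prevalence),
             cfg$mortality_none, cfg$mortality_stage,
             cfg$critical_care_none, cfg$critical_care_stage,
             cfg$rrt_stage3, cfg$anuria_stage3, cfg$maternity_rate,
             cfg$short_stay_rate, cfg$maintenance_dialysis_rate,
             cfg$single_test_rate)
  if (any(probs < 0 | probs > 1))
    stop("config probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(cfg$stage_mix) - 1) > 1e-8)
    stop("stage_mix must sum to 1", call. = FALSE)
  if (cfg$n_admissions < 1) stop("n_admissions must be >= 1", call. = FALSE)
  if (length(cfg$los_meanlog_stage) != 3 || length(cfg$mortality_stage) != 3 ||
      length(cfg$critical_care_stage) != 3)
    stop("per-stage parameter vectors must have length 3", call. = FALSE)
  invisible(cfg)
}

# Per-patient creatinine-ratio thresholds at which each target system
# first reaches stages 1..3 from the given baseline; used to back-solve a
# peak that lands strictly inside the desired stage band.
stage_ratio_thresholds <- function(system, baseline, age, sex, black) {
  cr_thr <- c(1.5, 2, 3)
  if (system != "RIFLE") return(cr_thr)
  # RIFLE: the eGFR-decline rules (>25/50/75%) bite at ratios solving
  # egfr(b * r) = baseline_egfr * (1 - q), i.e. r = (E(b)/(be(1-q)))^(1/1.154)
  eb <- mdrd_egfr(baseline$creatinine, age, sex, black)
  r_q <- (eb / (baseline$egfr * (1 - c(0.25, 0.50, 0.75))))^(1 / 1.154)
  pmin(cr_thr, pmax(r_q, 1.01))
}

# Interior point of the (lo, hi) stage band on the ratio scale.
band_point <- function(lo, hi) {
  if (is.infinite(hi)) return(lo * 1.18)
  x <- lo * 1.08
  if (x > hi * 0.92) sqrt(lo * hi) else x
}

#' Synthesize a creatinine trajectory that stages to a given verdict
#'
#' Builds a piecewise-linear rise-peak-recovery trajectory with
#' multiplicative log-normal noise whose staging-engine verdict for
#' `target_system` is exactly `target_stage` (round-trip property).  The
#' candidate series is replayed through [classify_admission()] — with the
#' baseline recomputed from the prior measurements exactly as the audit
#' pipeline will — and regenerated with shrinking noise on mismatch; the
#' final fallback is noiseless, for which the band construction guarantees
#' the verdict.  Stage-0 trajectories must stage 0 under all three
#' systems.
#'
#' @param baseline A [baseline_function()] (the intended reference).
#' @param target_system `"RIFLE"`, `"AKIN"` or `"AKIB"` (ignored for
#'   stage 0).
#' @param target_stage Integer 0-3.
#' @param los_days Length of stay in days (>= 3 for post-admission AKI).
#' @param admission_time `POSIXct` admission time.
#' @param prior Prior-measurement data frame (`timestamp`, `creatinine`)
#'   used to replay baseline determination; may be empty.
#' @param timing `"pre"` (criterion met by the admission sample) or
#'   `"post"`.
#' @param age,sex,black Demographics (RIFLE eGFR rules).
#' @param known_renal_impairment Passed to [determine_baseline()] replay.
#' @param anuria_hours,any_rrt Admission facts replayed alongside the labs.
#' @param sampling_rate Measurements per day after the rise phase.
#' @param noise_sd Log-scale noise SD.
#' @param single_test Emit only the admission sample (stage 0 only).
#' @param start_level Multiplier on the baseline giving the series'
#'   resting level around admission (mild acute elevation above the
#'   healthy nadir).
#' @param max_tries Noisy attempts before the noiseless fallback.
#' @return A [lab_series()] of in-hospital measurements.
#' @export
generate_trajectory <- function(baseline, target_system = "AKIN",
                                target_stage = 0, los_days = 7,
                                admission_time = as.POSIXct("2013-09-02 08:00:00", tz = "UTC"),
                                prior = NULL, timing = "post",
                                age = 60, sex = "M", black = FALSE,
                                known_renal_impairment = FALSE,
                                anuria_hours = 0, any_rrt = FALSE,
                                sampling_rate = 1, noise_sd = 0.04,
                                single_test = FALSE, start_level = 1,
                                max_tries = 20) {
  stopifnot(baseline$creatinine > 0, target_stage %in% 0:3)
  if (target_stage > 0 && single_test)
    stop("a single-measurement series cannot carry an AKI episode", call. = FALSE)
  b <- baseline$creatinine
  # Resting level of the series around admission; acutely admitted
  # patients typically run slightly above their healthy nadir.
  lvl <- b * start_level

  # Trend on an hour grid: admission sample, optional nadir/peak pair,
  # then sampling through the stay.
  build_trend <- function() {
    horizon <- 24 * min(los_days, 12)
    if (target_stage == 0) {
      tt <- if (single_test) 0 else
        unique(c(0, seq(24, max(24, horizon), by = 24 / sampling_rate)))
      return(list(t = tt, v = rep(lvl, length(tt)), peak_i = NA_integer_))
    }
    if (target_system == "AKIB") {
      rise <- c(34, 62, 115)[target_stage]
      t_nadir <- 24; t_peak <- 42            # 18 h rise, inside the 24 h window
      peak <- lvl + rise
    } else {
      thr <- stage_ratio_thresholds(target_system, baseline, age, sex, black)
      lo <- thr[target_stage]
      hi <- if (target_stage < 3) thr[target_stage + 1] else Inf
      r <- band_point(lo, hi)
      peak <- b * r
      t_nadir <- 24; t_peak <- 60            # 36 h rise, inside the 48 h window
    }
    if (timing == "pre") {
      tt <- unique(c(0, seq(24, max(48, horizon), by = 24 / sampling_rate)))
      v <- pmax(lvl, peak * 0.85^(tt / 24))  # recovery from the admission peak
      v[1] <- peak
      return(list(t = tt, v = v, peak_i = 1L))
    }
    later <- seq(t_peak + 24, max(t_peak + 48, horizon), by = 24 / sampling_rate)
    tt <- c(0, t_nadir, t_peak, later)
    v <- c(lvl, lvl, peak, pmax(lvl, peak * 0.85^((later - t_peak) / 24)))
    list(t = tt, v = v, peak_i = 3L)
  }

  replay <- function(series) {
    adm_val <- series$creatinine[1]
    bl <- determine_baseline(prior, adm_val, admission_time,
                             known_renal_impairment, sex, age, black)
    classify_admission(
      list(age = age, sex = sex, black = black, anuria_hours = anuria_hours,
           acute_rrt = any_rrt),
      series, bl
    )
  }

  trend <- build_trend()
  for (try in seq_len(max_tries + 1L)) {
    sd_try <- if (try > max_tries) 0 else noise_sd * 0.5^((try - 1) %/% 5)
    v <- trend$v * exp(stats::rnorm(length(trend$v), 0, sd_try))
    if (!is.na(trend$peak_i)) v[trend$peak_i] <- trend$v[trend$peak_i]
    v <- pmax(v, 20)
    series <- lab_series(admission_time + trend$t * 3600, v, "in-hospital")
    verdict <- replay(series)
    ok <- if (target_stage == 0) all(verdict$stage == 0) else
      verdict$stage[verdict$system == target_system] == target_stage
    if (ok) return(series)
  }
  stop(sprintf(
    "could not realise %s stage %d from baseline %.0f umol/L (timing %s)",
    target_system, target_stage, b, timing), call. = FALSE)
}

#' Generate a reproducible synthetic admission cohort
#'
#' Draws demographics and comorbidities, assigns AKI status from the
#' configured logistic risk model (intercept solved so the mean risk
#' equals the target incidence), assigns each AKI episode a stage,
#' criterion set and timing, synthesizes creatinine trajectories that
#' stage to exactly the assigned verdict (verified by replaying the
#' staging engine), and samples length of stay, critical care, mortality
#' and RRT from stage-conditional distributions.  A single seeded RNG
#' stream drives all draws, so the same config yields byte-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return List of class `"aki_cohort"`: `admissions` (one row per
#'   admission), `labs` (one row per creatinine measurement), and
#'   `assignments` (`admission_id`, `target_system`, `target_stage`,
#'   `timing_intent`, `analysed`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_admissions
  pv <- config$prevalence

  week <- sample(rep_len(1:2, n))
  week_start <- as.POSIXct(c("2013-09-02 00:00:00", "2014-02-03 00:00:00"),
                           tz = "UTC")[week]
  admission_time <- week_start + stats::runif(n, 0, 7 * 86400)

  age <- round(pmin(99, pmax(18, stats::rnorm(n, config$age_mean, config$age_sd))))
  sex <- ifelse(stats::runif(n) < config$male_frac, "M", "F")
  ethnicity <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                      prob = c(0.789, 0.067, 0.126, 0.018))
  black <- ethnicity == "black"
  route <- sample(c("emergency-department", "medical-admissions-unit",
                    "surgical-assessment-unit", "other"), n, replace = TRUE,
                  prob = c(0.862, 0.074, 0.015, 0.049))
  specialty <- sample(c("general-medicine", "general-surgery",
                        "tertiary-medicine", "tertiary-surgery"), n,
                      replace = TRUE, prob = c(0.63, 0.271, 0.031, 0.068))

  flag <- function(p) stats::runif(n) < p
  diabetes <- flag(pv$diabetes); hypertension <- flag(pv$hypertension)
  known_ckd <- flag(pv$known_ckd)
  ckd45 <- known_ckd & flag(pv$ckd45 / max(pv$known_ckd, 1e-9))
  nsaid <- flag(pv$nsaid); acei_arb <- flag(pv$acei_arb)
  diuretic <- flag(pv$diuretic); contrast <- flag(pv$contrast)
  sepsis <- flag(pv$sepsis)
  maternity <- flag(config$maternity_rate)
  maintenance_dialysis <- !maternity & flag(config$maintenance_dialysis_rate)
  short_stay <- !maternity & !maintenance_dialysis & flag(config$short_stay_rate)
  analysed <- !maternity & !maintenance_dialysis & !short_stay

  # Logistic AKI risk; intercept solved so mean risk = target incidence
  # over the analysed admissions.
  lo <- config$log_odds
  eta <- lo$ckd * known_ckd + lo$sepsis * sepsis + lo$diuretic * diuretic +
    lo$age_per_year * (age - 60)
  target <- config$target_incidence
  if (target == 0) {
    alpha <- -Inf
  } else {
    alpha <- stats::uniroot(function(a)
      mean(stats::plogis(a + eta[analysed])) - target, c(-20, 10))$root
  }
  aki <- analysed & (stats::runif(n) < stats::plogis(alpha + eta))

  stage <- integer(n)
  stage[aki] <- sample(1:3, sum(aki), replace = TRUE, prob = config$stage_mix)
  systems <- names(config$system_weights)
  target_system <- rep(NA_character_, n)
  target_system[aki] <- sample(systems, sum(aki), replace = TRUE,
                               prob = config$system_weights)

  known_baseline <- analysed & flag(config$fraction_known_baseline)
  timing_intent <- rep("none", n)
  pre <- aki & flag(config$frac_pre_admission)
  # AKIB has no assumed-baseline rule, and an admission-valued reference
  # cannot show a pre-admission rise: force those episodes post-admission.
  pre[aki & (target_system == "AKIB" |
               (!known_baseline & known_ckd))] <- FALSE
  timing_intent[aki] <- ifelse(pre[aki], "pre", "post")

  los <- numeric(n)
  los[!aki] <- pmax(1.2, stats::rlnorm(sum(!aki), config$los_meanlog_none,
                                       config$los_sdlog))
  if (any(aki))
    los[aki] <- pmax(4, stats::rlnorm(sum(aki),
                                      config$los_meanlog_stage[stage[aki]],
                                      config$los_sdlog))
  los[short_stay] <- stats::runif(sum(short_stay), 0.2, 0.9)

  acute_rrt <- aki & stage == 3 & flag(config$rrt_stage3)
  anuria_hours <- numeric(n)
  anuric <- aki & stage == 3 & flag(config$anuria_stage3)
  anuria_hours[anuric] <- stats::runif(sum(anuric), 14, 40)
  oliguria <- flag(pv$oliguria)

  p_die <- ifelse(aki, config$mortality_stage[pmax(stage, 1)], config$mortality_none)
  died <- stats::runif(n) < p_die
  p_cc <- ifelse(aki, config$critical_care_stage[pmax(stage, 1)],
                 config$critical_care_none)
  critical_care <- stats::runif(n) < p_cc
  critical_care_los <- ifelse(critical_care,
                              pmin(los, stats::rlnorm(n, log(3), 0.5)), 0)
  dialysis_dependent <- acute_rrt & !died & flag(0.15)

  # Sepsis components consistent with the two-of-three audit definition.
  wcc <- crp <- max_temp <- numeric(n)
  for (i in seq_len(n)) {
    m <- if (sepsis[i]) sample(2:3, 1, prob = c(0.7, 0.3)) else
      sample(0:1, 1, prob = c(0.7, 0.3))
    met <- sample(c(rep(TRUE, m), rep(FALSE, 3 - m)))
    wcc[i] <- if (met[1]) {
      if (stats::runif(1) < 0.3) stats::runif(1, 1.5, 3.8) else stats::runif(1, 12.5, 25)
    } else stats::runif(1, 4.5, 11.5)
    crp[i] <- if (met[2]) stats::runif(1, 55, 300) else stats::runif(1, 1, 45)
    max_temp[i] <- if (met[3]) stats::runif(1, 38.2, 39.8) else stats::runif(1, 36, 37.8)
  }

  # Baselines and prior measurements.
  base_cr <- ifelse(sex == "M", 80, 65) *
    exp(stats::rnorm(n, 0, 0.18)) * ifelse(known_ckd, 1.8, 1)
  base_cr <- round(pmin(280, pmax(45, base_cr)))
  base_cr[maintenance_dialysis] <- round(stats::runif(sum(maintenance_dialysis), 400, 800))

  admission_id <- sprintf("ADM%05d", seq_len(n))
  labs_list <- vector("list", n)
  for (i in seq_len(n)) {
    prior <- if (known_baseline[i]) {
      data.frame(timestamp = admission_time[i] -
                   stats::runif(1, 7, 180) * 86400,
                 creatinine = base_cr[i])
    } else {
      data.frame(timestamp = as.POSIXct(character()), creatinine = numeric())
    }
    if (analysed[i]) {
      intended <- if (known_baseline[i]) {
        baseline_function(base_cr[i],
                          mdrd_egfr(base_cr[i], age[i], sex[i], black[i]),
                          "measured-prior", prior$timestamp[1])
      } else if (known_ckd[i]) {
        baseline_function(base_cr[i],
                          mdrd_egfr(base_cr[i], age[i], sex[i], black[i]),
                          "admission", admission_time[i])
      } else {
        baseline_function(assumed_normal_creatinine(sex[i]), 75, "assumed-normal")
      }
      # Patients without history stage against the assumed-normal value,
      # so their trajectories start from it.
      series <- generate_trajectory(
        intended,
        target_system = if (aki[i]) target_system[i] else "AKIN",
        target_stage = stage[i], los_days = los[i],
        admission_time = admission_time[i], prior = prior,
        timing = timing_intent[i], age = age[i], sex = sex[i],
        black = black[i], known_renal_impairment = known_ckd[i],
        anuria_hours = anuria_hours[i], any_rrt = acute_rrt[i],
        sampling_rate = config$sampling_rate, noise_sd = config$noise_sd,
        single_test = !aki[i] && stats::runif(1) < config$single_test_rate,
        start_level = if (known_baseline[i]) 1.05 else 1
      )
    } else {
      # Excluded admissions (maternity / short-stay / dialysis) get a
      # single admission sample; they never reach the staging engine.
      series <- lab_series(admission_time[i],
                           pmax(20, base_cr[i] * exp(stats::rnorm(1, 0, config$noise_sd))),
                           "in-hospital")
    }
    pre_rows <- if (nrow(prior)) data.frame(
      patient_id = admission_id[i], timestamp = prior$timestamp,
      creatinine_umol_l = prior$creatinine, setting = "pre-admission") else NULL
    labs_list[[i]] <- rbind(pre_rows, data.frame(
      patient_id = admission_id[i], timestamp = series$timestamp,
      creatinine_umol_l = series$creatinine, setting = "in-hospital"))
  }

  admissions <- data.frame(
    admission_id = admission_id, age = age, sex = sex, ethnicity = ethnicity,
    admission_time = admission_time,
    discharge_time = admission_time + los * 86400,
    route = route, specialty = specialty, week = week,
    maternity = maternity, maintenance_dialysis = maintenance_dialysis,
    known_ckd = known_ckd, ckd45 = ckd45, diabetes = diabetes,
    hypertension = hypertension, nsaid = nsaid, acei_arb = acei_arb,
    diuretic = diuretic, contrast = contrast,
    wcc = round(wcc, 1), crp = round(crp), max_temp = round(max_temp, 1),
    anuria_hours = round(anuria_hours, 1), oliguria = oliguria,
    acute_rrt = acute_rrt, critical_care = critical_care,
    critical_care_los = round(critical_care_los, 1), died = died,
    dialysis_dependent_at_discharge = dialysis_dependent,
    stringsAsFactors = FALSE
  )
  labs <- do.call(rbind, labs_list)
  rownames(labs) <- NULL

  structure(list(
    admissions = admissions, labs = labs,
    assignments = data.frame(
      admission_id = admission_id,
      target_system = ifelse(aki, target_system, NA_character_),
      target_stage = ifelse(analysed, stage, NA_integer_),
      timing_intent = timing_intent, analysed = analysed,
      stringsAsFactors = FALSE
    ),
    config = config
  ), class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("Synthetic cohort: %d admissions (%d analysed), %d with assigned AKI\n",
              nrow(x$admissions), sum(a$analysed),
              sum(a$target_stage >= 1, na.rm = TRUE)))
  cat(sprintf("  labs: %d creatinine measurements; seed %d\n",
              nrow(x$labs), x$config$seed))
  invisible(x)
}
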
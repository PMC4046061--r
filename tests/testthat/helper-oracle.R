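# Brute-force staging oracle: literal all-ordered-pairs evaluation of the
# three criterion sets, written independently of the package's
# rolling-nadir engine.  Times are hours from admission; the baseline is a
# plain list (creatinine, egfr, source, bt_h = reference time in hours,
# NA when unknown).

oracle_egfr <- function(v, age, sex, black) {
  175 * (v / 88.4)^(-1.154) * age^(-0.203) *
    (if (sex == "F") 0.742 else 1) * (if (black) 1.212 else 1)
}

# All eligible (measurement i, reference) pairs for a window w (hours).
# A reference is an earlier-or-equal measurement with t_i - t_ref < w, or
# the baseline when: its time lies in (t_i - w, t_i]; its time is unknown
# (assumed-normal); or i == 1 (the pre-admission assumption).
oracle_pairs <- function(t_h, v, e, bl, w, age, sex, black) {
  out <- list()
  for (i in seq_along(t_h)) {
    for (j in seq_len(i)) {
      if (t_h[j] > t_h[i] - w) {
        out[[length(out) + 1L]] <- list(val = v[i], ref = v[j],
                                        e_val = e[i], e_ref = e[j])
      }
    }
    b_elig <- is.na(bl$bt_h) || bl$source == "assumed-normal" ||
      (bl$bt_h > t_h[i] - w && bl$bt_h <= t_h[i]) || i == 1L
    if (b_elig) {
      out[[length(out) + 1L]] <- list(val = v[i], ref = bl$creatinine,
                                      e_val = e[i], e_ref = bl$egfr)
    }
  }
  out
}

oracle_rifle <- function(t_h, v, bl, age, sex, black = FALSE, anuria_h = 0) {
  e <- oracle_egfr(v, age, sex, black)
  stage <- 0L
  for (p in oracle_pairs(t_h, v, e, bl, 7 * 24, age, sex, black)) {
    r <- p$val / p$ref
    dec <- 100 * (1 - p$e_val / p$e_ref)
    stage <- max(stage,
                 (r > 1.5) + (r > 2) + (r > 3),
                 (dec > 25) + (dec > 50) + (dec > 75))
  }
  if (anuria_h > 12) stage <- 3L
  stage
}

oracle_akin <- function(t_h, v, bl, age, sex, black = FALSE, anuria_h = 0,
                        rrt = FALSE) {
  e <- oracle_egfr(v, age, sex, black)
  stage <- 0L
  for (p in oracle_pairs(t_h, v, e, bl, 48, age, sex, black)) {
    r <- p$val / p$ref
    rise <- p$val - p$ref
    stage <- max(stage, (r > 1.5) + (r > 2) + (r > 3))
    if (rise > 26) stage <- max(stage, 1L)
    if (p$ref > 300 && rise > 44) stage <- max(stage, 3L)
  }
  if (rrt || anuria_h > 12) stage <- 3L
  stage
}

oracle_akib <- function(t_h, v, bl) {
  if (bl$source == "measured-prior" && !is.na(bl$bt_h) && bl$bt_h < t_h[1]) {
    t_h <- c(bl$bt_h, t_h)
    v <- c(bl$creatinine, v)
  }
  stage <- 0L
  for (i in seq_along(t_h)) {
    for (j in seq_len(i)) {
      rise <- v[i] - v[j]
      dt <- t_h[i] - t_h[j]
      if (dt < 24) stage <- max(stage, (rise > 26) + (rise > 44) + (rise > 88))
      if (dt < 48) stage <- max(stage, (rise > 44) + (rise > 88) + (rise > 132))
    }
  }
  stage
}

oracle_classify <- function(t_h, v, bl, age = 60, sex = "M", black = FALSE,
                            anuria_h = 0, rrt = FALSE) {
  c(RIFLE = oracle_rifle(t_h, v, bl, age, sex, black, anuria_h),
    AKIN = oracle_akin(t_h, v, bl, age, sex, black, anuria_h, rrt),
    AKIB = oracle_akib(t_h, v, bl))
}

# Random staging scenario with values spread around the stage thresholds.
random_scenario <- function() {
  n <- sample(1:8, 1)
  t_h <- sort(sample(seq(0, 240, by = 0.5), n))
  b <- runif(1, 40, 420)
  v <- round(b * runif(n, 0.4, 4.2), 1)
  source <- sample(c("measured-prior", "admission", "assumed-normal"), 1)
  if (source == "assumed-normal") {
    sex <- sample(c("F", "M"), 1)
    cr <- if (sex == "F") 60 else 80
    bl <- list(creatinine = cr, egfr = 75, source = source, bt_h = NA_real_)
  } else {
    sex <- sample(c("F", "M"), 1)
    bt_h <- if (source == "admission") t_h[1] else
      t_h[1] - round(runif(1, 1, 150 * 24))
    bl <- list(creatinine = b, egfr = NA, source = source, bt_h = bt_h)
  }
  list(t_h = t_h, v = v, bl = bl, sex = sex,
       age = sample(18:95, 1), black = runif(1) < 0.1,
       anuria_h = if (runif(1) < 0.1) runif(1, 4, 30) else 0,
       rrt = runif(1) < 0.05)
}

# Run one scenario through both the engine and the oracle; returns a
# named logical vector of per-system agreement.
scenario_agrees <- function(sc, origin = as.POSIXct("2020-03-01 00:00:00", tz = "UTC")) {
  bl_obj <- baseline_function(
    sc$bl$creatinine,
    if (sc$bl$source == "assumed-normal") 75 else
      mdrd_egfr(sc$bl$creatinine, sc$age, sc$sex, sc$black),
    sc$bl$source,
    if (is.na(sc$bl$bt_h)) as.POSIXct(NA) else origin + sc$bl$bt_h * 3600
  )
  sc$bl$egfr <- bl_obj$egfr
  series <- lab_series(origin + sc$t_h * 3600, sc$v, "in-hospital")
  got <- classify_admission(
    list(age = sc$age, sex = sc$sex, black = sc$black,
         anuria_hours = sc$anuria_h, acute_rrt = sc$rrt),
    series, bl_obj
  )
  want <- oracle_classify(sc$t_h, sc$v, sc$bl, sc$age, sc$sex, sc$black,
                          sc$anuria_h, sc$rrt)
  stats::setNames(got$stage == want[got$system], got$system)
}
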
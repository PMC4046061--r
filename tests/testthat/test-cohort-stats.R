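make_admissions <- function(n, los_days = 5) {
  data.frame(
    admission_id = sprintf("A%03d", seq_len(n)),
    admission_time = T0,
    discharge_time = T0 + rep_len(los_days, n) * 86400,
    maternity = FALSE, maintenance_dialysis = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("cohort assembly applies the audit exclusions", {
  adm <- make_admissions(745)
  adm$maintenance_dialysis[1:17] <- TRUE
  out <- assemble_cohort(adm)
  expect_equal(nrow(out$cohort), 728)
  expect_equal(sum(out$exclusions$reason == "maintenance-dialysis"), 17)

  # a 20-hour stay is excluded as short-stay; CKD 4/5 patients stay in
  adm2 <- make_admissions(3)
  adm2$discharge_time[1] <- T0 + 20 * 3600
  adm2$ckd45 <- c(FALSE, TRUE, FALSE)
  out2 <- assemble_cohort(adm2)
  expect_equal(out2$exclusions$reason, "short-stay")
  expect_true("A002" %in% out2$cohort$admission_id)
  expect_equal(out2$cohort$los_days, c(5, 5))
})

test_that("empty input gives an empty cohort and empty exclusion report", {
  out <- assemble_cohort(make_admissions(1)[0, ])
  expect_equal(nrow(out$cohort), 0)
  expect_equal(nrow(out$exclusions), 0)
})

test_that("duplicate admission ids are a validation error", {
  adm <- make_admissions(4)
  adm$admission_id[2] <- adm$admission_id[1]
  expect_error(assemble_cohort(adm), "duplicate")
})

test_that("sepsis requires at least two of three indicators", {
  expect_true(sepsis_flag(13.5, 80, 37.2))    # WCC + CRP
  expect_false(sepsis_flag(8.0, 20, 37.0))    # none
  expect_true(sepsis_flag(3.5, 10, 38.5))     # low WCC + pyrexia
  # full enumeration of met/not-met combinations against the >= 2 rule
  wcc <- c(met = 14, not = 8); crp <- c(met = 80, not = 10)
  tmp <- c(met = 38.6, not = 37)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    expect_identical(unname(sepsis_flag(wcc[i], crp[j], tmp[k])),
                     sum(c(i, j, k) == 1) >= 2)
  }
  # missing components count as not met
  expect_false(sepsis_flag(NA, 80, NA))
  expect_true(sepsis_flag(NA, 80, 39))
})

test_that("incidence table reproduces published percentages from counts", {
  stages <- rep(c(0L, 1L, 2L, 3L), c(728 - 172, 104, 48, 20))
  tab <- incidence_table(stages, 728, "RIFLE")
  expect_equal(tab$count, c(556, 104, 48, 20, 172))
  expect_equal(tab$pct, c(76.4, 14.3, 6.6, 2.7, 23.6))
  # percentages recompute from counts and counts conserve the cohort
  expect_equal(sum(tab$count[1:4]), 728)
  expect_equal(tab$pct, round(100 * tab$count / 728, 1), tolerance = 0.051)
})

test_that("incidence table handles degenerate inputs", {
  tab0 <- incidence_table(integer(), 50)
  expect_equal(tab0$count, c(50, 0, 0, 0, 0))
  expect_equal(tab0$pct[5], 0)
  tab1 <- incidence_table(c(1L, 2L, 3L), 10)
  expect_equal(tab1$pct, c(70, 10, 10, 10, 30))
  expect_error(incidence_table(rep(1L, 11), 10), "more episodes")
})

test_that("exact binomial intervals match published values", {
  expect_equal(round(binomial_ci(5, 20), 1), c(lower = 8.7, upper = 49.1))
  expect_equal(round(binomial_ci(4, 20), 1), c(lower = 5.7, upper = 43.7))
  expect_equal(binomial_ci(0, 20)[["lower"]], 0)
  expect_equal(binomial_ci(20, 20)[["upper"]], 100)
  expect_error(binomial_ci(1, 0), "undefined")
  expect_error(binomial_ci(5, 4))
})

test_that("Clopper-Pearson intervals are conservative (coverage >= 95%)", {
  set.seed(19)
  p <- 0.2; n <- 20
  k <- rbinom(10000, n, p)
  # interval bounds depend only on k: tabulate coverage over 0..n
  covered <- vapply(0:n, function(kk) {
    ci <- binomial_ci(kk, n, percent = FALSE)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(covered[k + 1]), 0.95)
})

test_that("odds ratios reproduce the published mortality comparisons", {
  # death: 21/185 with AKI vs 18/543 without
  m <- odds_ratio(21, 164, 18, 525)
  expect_equal(round(m$or, 1), 3.7)
  expect_equal(round(m$ci[1], 2), 1.94)
  expect_lt(m$p_midp, 1e-3)
  # stage-2 (RIFLE Injury) deaths 7/48 vs 20/556
  s2 <- odds_ratio(7, 41, 20, 536)
  expect_equal(round(s2$or, 1), 4.6)
  expect_equal(round(s2$p_midp, 3), 0.004)
  # stage-3 deaths 5/20 vs 20/556
  s3 <- odds_ratio(5, 15, 20, 536)
  expect_equal(round(s3$p_midp, 3), 0.001)
})

test_that("odds-ratio identities and edge cases hold", {
  expect_equal(odds_ratio(5, 5, 5, 5)$or, 1)
  # flipping the outcome inverts the OR exactly
  set.seed(5)
  for (k in 1:20) {
    x <- sample(1:40, 4)
    expect_equal(odds_ratio(x[1], x[2], x[3], x[4])$or *
                   odds_ratio(x[2], x[1], x[4], x[3])$or, 1)
  }
  z <- odds_ratio(0, 10, 5, 5)
  expect_true(is.na(z$or) || z$or == 0)
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("repeat-testing flag follows the eGFR < 60 rule", {
  s1 <- series_at(0, 160)
  expect_true(repeat_testing_flag(s1, 45, NULL))
  expect_false(repeat_testing_flag(series_at(c(0, 24), c(160, 150)), 45, NULL))
  expect_false(repeat_testing_flag(s1, 80, NULL))
  # unchanged from a documented six-month baseline: no repeat needed
  bl <- baseline_at(158, hours_before = 6 * 7 * 24)
  expect_false(repeat_testing_flag(s1, 45, bl))
  bl2 <- baseline_at(100, hours_before = 6 * 7 * 24)
  expect_true(repeat_testing_flag(s1, 45, bl2))
})
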
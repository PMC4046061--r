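test_that("the reference configuration encodes the audit's marginal rates", {
  cfg <- reference_config()
  expect_equal(cfg$target_incidence, 0.254)
  expect_equal(cfg$mortality_none, 0.033)
  expect_equal(cfg$fraction_known_baseline, 0.457)
  expect_equal(sum(cfg$stage_mix), 1)
  expect_silent(akiaudit:::validate_cohort_config(cfg))
  expect_error(cohort_config(target_incidence = 1.4), "\\[0, 1\\]")
  expect_error(cohort_config(stage_mix = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("the same config and seed give byte-identical cohorts; different seeds differ", {
  cfg <- reference_config(n_admissions = 60, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("admissions.csv", "labs.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  c3 <- generate_cohort(reference_config(n_admissions = 60, seed = 6))
  expect_false(identical(c1$labs$creatinine_umol_l, c3$labs$creatinine_umol_l))
})

test_that("a zero-incidence configuration yields a cohort with no AKI episodes", {
  cfg <- reference_config(n_admissions = 80, seed = 2, target_incidence = 0,
                          maternity_rate = 0, short_stay_rate = 0,
                          maintenance_dialysis_rate = 0)
  co <- generate_cohort(cfg)
  rep <- run_audit(co$admissions, co$labs)
  expect_equal(rep$union_incidence$count, 0)
  expect_true(all(rep$episodes$stage == 0))
})

test_that("trajectories stage to exactly the requested verdict", {
  set.seed(31)
  bl <- baseline_at(100, hours_before = 20 * 24)
  prior <- data.frame(timestamp = T0 - 20 * 86400, creatinine = 100)
  s <- generate_trajectory(bl, "AKIN", 2, los_days = 7, admission_time = T0,
                           prior = prior, timing = "post")
  ep <- classify_admission(demo_admission(), s,
                           determine_baseline(prior, s$creatinine[1], T0,
                                              sex = "M", age = 60))
  expect_equal(ep$stage[ep$system == "AKIN"], 2L)

  # stage 0: flat-with-noise, stage 0 under every system
  s0 <- generate_trajectory(bl, target_stage = 0, los_days = 5,
                            admission_time = T0, prior = prior)
  ep0 <- classify_admission(demo_admission(), s0,
                            determine_baseline(prior, s0$creatinine[1], T0,
                                               sex = "M", age = 60))
  expect_true(all(ep0$stage == 0L))

  # RIFLE Failure from baseline 80 needs a peak beyond 240 within 7 days
  bl80 <- baseline_function(80, 75, "assumed-normal")
  s3 <- generate_trajectory(bl80, "RIFLE", 3, los_days = 8, admission_time = T0,
                            prior = NULL, timing = "post")
  expect_gt(max(s3$creatinine), 240)
  ep3 <- classify_admission(demo_admission(), s3,
                            determine_baseline(NULL, s3$creatinine[1], T0,
                                               sex = "M", age = 60))
  expect_equal(ep3$stage[ep3$system == "RIFLE"], 3L)
})

test_that("stage-1 requests cannot be asked of a single-measurement series", {
  bl <- baseline_function(80, 75, "assumed-normal")
  expect_error(generate_trajectory(bl, "AKIN", 1, single_test = TRUE),
               "single-measurement")
})

test_that("generated stages round-trip through the staging engine", {
  cfg <- reference_config(n_admissions = 300, seed = 8, maternity_rate = 0,
                          short_stay_rate = 0, maintenance_dialysis_rate = 0)
  co <- generate_cohort(cfg)
  rep <- run_audit(co$admissions, co$labs)
  a <- co$assignments
  ep <- rep$episodes
  aki <- a[!is.na(a$target_system), ]
  m <- merge(aki, ep, by.x = c("admission_id", "target_system"),
             by.y = c("admission_id", "system"))
  expect_equal(nrow(m), nrow(aki))
  expect_true(all(m$stage == m$target_stage))
  # assigned stage-0 admissions stage 0 under every system
  zero_ids <- a$admission_id[a$target_stage == 0]
  expect_true(all(ep$stage[ep$admission_id %in% zero_ids] == 0))
  # union incidence equals the assigned AKI count exactly
  expect_equal(rep$union_incidence$count, nrow(aki))
})

test_that("sepsis components in the generated cohort reproduce the audit flag", {
  co <- generate_cohort(reference_config(n_admissions = 150, seed = 12))
  adm <- co$admissions
  flags <- sepsis_flag(adm$wcc, adm$crp, adm$max_temp)
  # prevalence near the configured 15%
  expect_gt(mean(flags), 0.08)
  expect_lt(mean(flags), 0.25)
})
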
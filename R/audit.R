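#' Read admissions and laboratory CSV files
#'
#' The admissions file has one row per admission (see the README for the
#' full schema); the labs file has columns `patient_id`, `timestamp`
#' (ISO-8601), `creatinine_umol_l`, `setting`.  Dates are parsed strictly
#' as ISO-8601 in UTC.
#'
#' @param path CSV file path.
#' @return Data frame with parsed types.
#' @export
read_admissions_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("admission_id", "age", "sex", "admission_time", "discharge_time")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("admissions CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("admission_time", "discharge_time")) {
    parsed <- as.POSIXct(x[[col]], tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                        "%Y-%m-%d"))
    bad <- which(is.na(parsed) & !is.na(x[[col]]))
    if (length(bad))
      stop(sprintf("column '%s': unparseable ISO-8601 datetime at row %d",
                   col, bad[1]), call. = FALSE)
    x[[col]] <- parsed
  }
  x
}

#' @rdname read_admissions_csv
#' @export
read_labs_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "timestamp", "creatinine_umol_l", "setting")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("labs CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  parsed <- as.POSIXct(x$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                      "%Y-%m-%d"))
  bad <- which(is.na(parsed) & !is.na(x$timestamp))
  if (length(bad))
    stop(sprintf("column 'timestamp': unparseable ISO-8601 datetime at row %d",
                 bad[1]), call. = FALSE)
  x$timestamp <- parsed
  if (any(!is.finite(x$creatinine_umol_l) | x$creatinine_umol_l <= 0))
    stop("labs CSV: creatinine_umol_l must be positive", call. = FALSE)
  x
}

#' Write a synthetic cohort to CSV fixtures
#'
#' Emits `admissions.csv` and `labs.csv` in the schemas consumed by
#' [run_audit()], plus `config.json`-style resolved configuration as a
#' `config.dcf` text file.  Output is byte-identical for identical
#' (config, seed).
#'
#' @param cohort An `aki_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aki_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adm <- cohort$admissions
  adm$admission_time <- format(adm$admission_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  adm$discharge_time <- format(adm$discharge_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  labs <- cohort$labs
  labs$timestamp <- format(labs$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  labs$creatinine_umol_l <- round(labs$creatinine_umol_l, 1)
  paths <- file.path(dir, c("admissions.csv", "labs.csv", "config.dcf"))
  utils::write.csv(adm, paths[1], row.names = FALSE)
  utils::write.csv(labs, paths[2], row.names = FALSE)
  cfg <- cohort$config
  flat <- vapply(cfg, function(x) paste(deparse(unlist(x)), collapse = " "), "")
  writeLines(paste0(names(flat), ": ", flat), paths[3])
  invisible(paths)
}

#' Run the full AKI audit on an admissions + labs dataset
#'
#' Pipeline: assemble the analysis cohort (audit exclusions), determine
#' each admission's baseline renal function, stage every admission under
#' the requested criteria, then produce incidence tables (full cohort and
#' the known-baseline subgroup), the risk-factor models and the outcome
#' analysis.
#'
#' @param admissions Admissions data frame (or path to a CSV).
#' @param labs Labs data frame (or path to a CSV).
#' @param systems Criteria to evaluate.
#' @param risk_factors Columns used in the risk models (defaults to the
#'   audit set; missing columns are dropped with a notice).
#' @param stage_system System used for per-stage outcome tables.
#' @param verbose Log step counts to stderr.
#' @return List of class `"aki_audit_report"`.
#' @export
run_audit <- function(admissions, labs,
                      systems = c("RIFLE", "AKIN", "AKIB"),
                      risk_factors = c("known_ckd", "nsaid", "contrast",
                                       "acei_arb", "diuretic", "diabetes",
                                       "sepsis", "hypertension", "age", "week"),
                      stage_system = NULL, verbose = FALSE) {
  if (is.character(admissions)) admissions <- read_admissions_csv(admissions)
  if (is.character(labs)) labs <- read_labs_csv(labs)
  systems <- match.arg(systems, c("RIFLE", "AKIN", "AKIB"), several.ok = TRUE)
  if (is.null(stage_system)) stage_system <- systems[1]
  say <- function(...) if (verbose) message(sprintf(...))

  unknown <- setdiff(unique(labs$patient_id), admissions$admission_id)
  if (length(unknown))
    stop("labs refer to unknown patient_id: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  asm <- assemble_cohort(admissions)
  cohort <- asm$cohort
  say("assembled cohort: %d of %d admissions (%d excluded)",
      nrow(cohort), nrow(admissions), nrow(asm$exclusions))
  if (nrow(cohort) == 0L) {
    return(structure(list(empty = TRUE, exclusions = asm$exclusions,
                          note = "empty cohort: no admissions after exclusions"),
                     class = "aki_audit_report"))
  }

  if (!"sepsis" %in% names(cohort) &&
      all(c("wcc", "crp", "max_temp") %in% names(cohort)))
    cohort$sepsis <- sepsis_flag(cohort$wcc, cohort$crp, cohort$max_temp)

  # Baseline + staging per admission.
  lab_split <- split(labs, labs$patient_id)
  episodes <- vector("list", nrow(cohort))
  baseline_source <- character(nrow(cohort))
  repeat_flag <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    adm <- cohort[i, ]
    pl <- lab_split[[adm$admission_id]]
    inpt <- if (is.null(pl)) NULL else
      pl[pl$setting == "in-hospital", , drop = FALSE]
    if (is.null(inpt) || nrow(inpt) == 0L) {
      # Never tested: counted in the cohort denominator as no detected AKI.
      episodes[[i]] <- do.call(rbind, lapply(systems, function(sys)
        aki_episode(sys, 0L, timing = "none", admission_id = adm$admission_id)))
      baseline_source[i] <- "untested"
      next
    }
    inpt <- inpt[order(inpt$timestamp), ]
    prior_raw <- pl[pl$setting == "pre-admission", , drop = FALSE]
    prior <- data.frame(timestamp = prior_raw$timestamp,
                        creatinine = prior_raw$creatinine_umol_l)
    black <- identical(adm$ethnicity, "black") || isTRUE(adm$black)
    bl <- determine_baseline(prior, inpt$creatinine_umol_l[1],
                             adm$admission_time,
                             known_renal_impairment = isTRUE(adm$known_ckd),
                             sex = adm$sex, age = adm$age, black = black)
    baseline_source[i] <- bl$source
    series <- lab_series(inpt$timestamp, inpt$creatinine_umol_l, "in-hospital")
    episodes[[i]] <- classify_admission(adm, series, bl, systems = systems)
    repeat_flag[i] <- repeat_testing_flag(
      series, mdrd_egfr(inpt$creatinine_umol_l[1], adm$age, adm$sex, black), bl)
  }
  episodes <- do.call(rbind, episodes)
  say("staged %d admissions under %s", nrow(cohort),
      paste(systems, collapse = "/"))

  n <- nrow(cohort)
  incidence <- lapply(systems, function(sys)
    incidence_table(episodes[episodes$system == sys, ], n, sys))
  names(incidence) <- systems
  any_aki_n <- sum(tapply(episodes$stage, episodes$admission_id, max) >= 1)
  union_incidence <- list(count = any_aki_n, n = n,
                          pct = round_half_up(100 * any_aki_n / n, 1),
                          ci = round_half_up(binomial_ci(any_aki_n, n), 1))

  known <- baseline_source == "measured-prior"
  sub_ids <- cohort$admission_id[known]
  sub_ep <- episodes[episodes$admission_id %in% sub_ids, ]
  subgroup <- if (length(sub_ids)) {
    si <- lapply(systems, function(sys)
      incidence_table(sub_ep[sub_ep$system == sys, ], length(sub_ids), sys))
    names(si) <- systems
    sn <- sum(tapply(sub_ep$stage, sub_ep$admission_id, max) >= 1)
    list(n = length(sub_ids), incidence = si,
         union_incidence = list(count = sn, n = length(sub_ids),
                                pct = round_half_up(100 * sn / length(sub_ids), 1)))
  } else NULL

  aki <- cohort$admission_id %in%
    names(which(tapply(episodes$stage, episodes$admission_id, max) >= 1))
  rf_avail <- intersect(risk_factors, names(cohort))
  dropped <- setdiff(risk_factors, rf_avail)
  if (length(dropped)) say("risk factors not in data, dropped: %s",
                           paste(dropped, collapse = ", "))
  risk <- if (length(rf_avail) >= 1)
    risk_factor_analysis(cohort, aki, rf_avail) else NULL

  outcomes <- if (all(c("died", "critical_care") %in% names(cohort)))
    outcome_analysis(cohort, episodes, stage_system = stage_system) else NULL

  structure(list(
    empty = FALSE,
    cohort_n = n, total_admissions = nrow(admissions),
    exclusions = asm$exclusions,
    baseline_source = table(baseline_source),
    episodes = episodes,
    incidence = incidence, union_incidence = union_incidence,
    subgroup = subgroup,
    risk = risk, outcomes = outcomes,
    repeat_testing_missed = sum(repeat_flag),
    systems = systems
  ), class = "aki_audit_report")
}

#' @export
print.aki_audit_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("AKI audit report: empty cohort (nothing to analyse)\n")
    if (nrow(x$exclusions)) print(table(x$exclusions$reason))
    return(invisible(x))
  }
  cat(sprintf("AKI audit report: %d analysed of %d admissions (%d excluded)\n",
              x$cohort_n, x$total_admissions, nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    cat("  excluded:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  u <- x$union_incidence
  cat(sprintf("AKI by any criterion: %d/%d = %.1f%% (95%% CI %.1f to %.1f)\n",
              u$count, u$n, u$pct, u$ci[1], u$ci[2]))
  for (sys in x$systems) {
    t <- x$incidence[[sys]]
    cat(sprintf("  %s: stages 1/2/3 = %s; total %.1f%% (%d)\n", sys,
                paste(sprintf("%.1f%% (%d)", t$pct[2:4], t$count[2:4]),
                      collapse = ", "),
                t$pct[5], t$count[5]))
  }
  if (!is.null(x$subgroup))
    cat(sprintf("Known-baseline subgroup: n = %d, any-criterion AKI %.1f%%\n",
                x$subgroup$n, x$subgroup$union_incidence$pct))
  cat(sprintf("Single test despite indication for repeat: %d admissions\n",
              x$repeat_testing_missed))
  if (!is.null(x$outcomes)) { cat("\n"); print(x$outcomes) }
  invisible(x)
}

#' Write the audit report tables to CSV
#'
#' One CSV per table: incidence (per system, full cohort and subgroup),
#' mortality and critical-care stage tables, risk-factor estimates and the
#' exclusion log, plus a plain-text summary.
#'
#' @param report An `aki_audit_report`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "aki_audit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- character()
  if (!isTRUE(report$empty)) {
    paths <- c(paths, wr(do.call(rbind, report$incidence), "incidence.csv"))
    if (!is.null(report$subgroup))
      paths <- c(paths, wr(do.call(rbind, report$subgroup$incidence),
                           "incidence_known_baseline.csv"))
    paths <- c(paths, wr(report$episodes, "staging.csv"))
    if (!is.null(report$outcomes)) {
      paths <- c(paths, wr(report$outcomes$mortality$table, "mortality.csv"),
                 wr(report$outcomes$critical_care$table, "critical_care.csv"))
    }
    if (!is.null(report$risk))
      paths <- c(paths, wr(report$risk$multivariate, "risk_factors.csv"))
  }
  paths <- c(paths, wr(report$exclusions, "exclusions.csv"))
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con); print(report); sink()
  close(con)
  invisible(c(paths, summary_path))
}
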
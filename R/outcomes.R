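#' Length-of-stay, critical-care and mortality analysis by AKI status
#'
#' Reproduces the audit's outcome comparisons: median length of stay (LOS)
#' with a Mann-Whitney (Wilcoxon rank-sum) test for AKI vs no AKI and for
#' pre- vs post-admission AKI; a Kruskal-Wallis test and Spearman
#' correlation of LOS across stages; per-stage mortality and critical-care
#' tables with exact binomial confidence intervals; and AKI-vs-none odds
#' ratios for death and critical-care admission.
#'
#' @param cohort Assembled cohort data frame with `admission_id`,
#'   `los_days`, `died`, `critical_care`.
#' @param episodes Episode data frame from [classify_admission()] (all
#'   systems, all admissions); stages define AKI status.  An admission is
#'   "AKI" when any system stages it >= 1.
#' @param stage_system System whose stages grade the per-stage tables and
#'   trend tests (default `"RIFLE"`).
#' @return List of class `"outcome_analysis"`.
#' @export
outcome_analysis <- function(cohort, episodes, stage_system = "RIFLE") {
  stopifnot(all(c("admission_id", "los_days", "died", "critical_care") %in%
                  names(cohort)))
  if (any(cohort$los_days < 0)) stop("negative length of stay", call. = FALSE)
  bad <- setdiff(unique(episodes$admission_id), cohort$admission_id)
  if (length(bad))
    stop("episodes refer to admissions outside the cohort: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)

  # Per-admission union AKI flag and per-system stage.
  any_stage <- tapply(episodes$stage, episodes$admission_id, max)
  aki <- cohort$admission_id %in% names(any_stage)[any_stage >= 1]
  sys_ep <- episodes[episodes$system == stage_system, , drop = FALSE]
  stage <- stats::setNames(rep(0L, nrow(cohort)), cohort$admission_id)
  stage[sys_ep$admission_id] <- sys_ep$stage
  timing <- stats::setNames(rep("none", nrow(cohort)), cohort$admission_id)
  timing[sys_ep$admission_id] <- sys_ep$timing

  notices <- character()
  skip_or_test <- function(g1, g2, what) {
    if (length(g1) == 0L || length(g2) == 0L) {
      notices <<- c(notices, sprintf("%s: a group is empty, comparison skipped", what))
      return(list(p = NA_real_))
    }
    list(p = suppressWarnings(stats::wilcox.test(g1, g2)$p.value))
  }

  los <- cohort$los_days
  los_aki <- los[aki]; los_none <- los[!aki]
  mw_aki <- skip_or_test(los_aki, los_none, "LOS AKI vs none")
  los_pre <- los[timing[cohort$admission_id] == "pre-admission"]
  los_post <- los[timing[cohort$admission_id] == "post-admission"]
  mw_timing <- skip_or_test(los_pre, los_post, "LOS pre vs post")

  stg <- stage[cohort$admission_id]
  kw_p <- if (length(unique(stg)) > 1)
    stats::kruskal.test(los, factor(stg))$p.value else NA_real_
  rho <- suppressWarnings(
    stats::cor.test(stg, los, method = "spearman", exact = FALSE))

  or_of <- function(outcome) {
    odds_ratio(sum(outcome & aki), sum(!outcome & aki),
               sum(outcome & !aki), sum(!outcome & !aki))
  }

  structure(list(
    los = list(
      median_aki = stats::median(los_aki), median_none = stats::median(los_none),
      mann_whitney_p = mw_aki$p,
      median_pre = stats::median(los_pre), median_post = stats::median(los_post),
      timing_mann_whitney_p = mw_timing$p,
      kruskal_wallis_p = kw_p, spearman_rho = unname(rho$estimate),
      spearman_p = rho$p.value
    ),
    mortality = list(
      table = stage_outcome_table(stg, cohort$died, stage_system),
      or_aki = or_of(cohort$died)
    ),
    critical_care = list(
      table = stage_outcome_table(stg, cohort$critical_care, stage_system),
      or_aki = or_of(cohort$critical_care)
    ),
    aki = aki, stage = unname(stg), notices = notices,
    stage_system = stage_system
  ), class = "outcome_analysis")
}

#' @export
print.outcome_analysis <- function(x, ...) {
  l <- x$los
  cat(sprintf("Median LOS: %.1f d (AKI) vs %.1f d (no AKI); Mann-Whitney p = %.2g\n",
              l$median_aki, l$median_none, l$mann_whitney_p))
  cat(sprintf("Median LOS: %.1f d (pre-admission) vs %.1f d (post-admission); p = %.2g\n",
              l$median_pre, l$median_post, l$timing_mann_whitney_p))
  cat(sprintf("LOS across %s stages: Kruskal-Wallis p = %.2g, Spearman rho = %.2f\n",
              x$stage_system, l$kruskal_wallis_p, l$spearman_rho))
  m <- x$mortality$or_aki; cc <- x$critical_care$or_aki
  cat(sprintf("Mortality OR (AKI vs none): %.1f (%.2f to %.2f), mid-p = %.2g\n",
              m$or, m$ci[1], m$ci[2], m$p_midp))
  cat(sprintf("Critical-care OR (AKI vs none): %.1f (%.2f to %.2f), mid-p = %.2g\n",
              cc$or, cc$ci[1], cc$ci[2], cc$p_midp))
  for (n in x$notices) cat("note: ", n, "\n", sep = "")
  invisible(x)
}
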
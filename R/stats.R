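# Round half away from zero to d decimals (table-emission convention;
# base round() rounds half to even).
round_half_up <- function(x, d = 1) {
  floor(abs(x) * 10^d + 0.5) / 10^d * sign(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k Number of events (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @param percent Report bounds as percentages (default) or proportions.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' round(binomial_ci(5, 20), 1)  # 8.7 49.1
#' @export
binomial_ci <- function(k, n, level = 0.95, percent = TRUE) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n <= 0) stop("undefined: n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("'k' must lie in [0, n]", call. = FALSE)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  out <- c(lower = lo, upper = hi)
  if (percent) out * 100 else out
}

#' 2x2 contingency table for exposure/event counts
#'
#' @param a,b,c,d Non-negative integer counts: exposed with event, exposed
#'   without, unexposed with event, unexposed without.
#' @return Object of class `"contingency_2x2"`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(x < 0) || any(x != round(x))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(x), class = "contingency_2x2")
}

#' Odds ratio with Woolf confidence interval and mid-p exact test
#'
#' The point estimate is the cross-product ratio \eqn{ad/bc}; the
#' confidence interval uses the Woolf (log) method
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}; the p-value is
#' the two-sided mid-p exact test from the hypergeometric distribution of
#' the `a` cell given fixed margins.
#'
#' @param t A [contingency_2x2()], or `a` when the four counts are given
#'   positionally.
#' @param b,c,d Remaining cell counts when `t` is numeric.
#' @param level Confidence level for the Woolf interval.
#' @return List with `or`, `ci` (length-2), `p_midp`, and the table.
#' @examples
#' odds_ratio(21, 164, 18, 525)$or  # 3.73: odds of death, AKI vs no AKI
#' @export
odds_ratio <- function(t, b = NULL, c = NULL, d = NULL, level = 0.95) {
  if (is.numeric(t) && !is.null(b)) t <- contingency_2x2(t, b, c, d)
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (b * c == 0 || a * d == 0) {
    or <- if (b * c == 0) NA_real_ else 0
    return(list(or = or, ci = c(NA_real_, NA_real_),
                p_midp = midp_exact(a, b, c, d), table = t,
                note = "zero cell: odds ratio undefined"))
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se),
       p_midp = midp_exact(a, b, c, d), table = t)
}

# Two-sided mid-p exact test for a 2x2 table: hypergeometric tail
# probabilities for the a-cell with half weight on the observed table.
midp_exact <- function(a, b, c, d) {
  m <- a + b            # exposed margin
  k <- a + c            # event margin
  n_tot <- a + b + c + d
  lo <- max(0, k - (n_tot - m)); hi <- min(k, m)
  if (lo == hi) return(1)
  p_obs <- stats::dhyper(a, m, n_tot - m, k)
  p_lower <- stats::phyper(a - 1, m, n_tot - m, k) + 0.5 * p_obs
  p_upper <- 1 - stats::phyper(a, m, n_tot - m, k) + 0.5 * p_obs
  min(1, 2 * min(p_lower, p_upper))
}

#' Per-stage incidence table for one staging system
#'
#' Builds the count / percentage / exact-CI summary for a set of exclusive
#' per-admission episodes under one system.  Percentages are of the full
#' cohort and rounded half-up to 1 decimal; the `total` row pools stages
#' 1-3.
#'
#' @param episodes Episode data frame (as from [classify_admission()])
#'   already restricted to one system, or a vector of integer stages 0-3.
#' @param cohort_n Cohort size (denominator).  Admissions absent from
#'   `episodes` (e.g. never tested) count as stage 0.
#' @param system Label for the table.
#' @return Data frame of class `"stage_table"`: `stage`, `count`, `pct`,
#'   `ci_lower`, `ci_upper` with rows `0`, `1`, `2`, `3`, `total`.
#' @export
incidence_table <- function(episodes, cohort_n, system = "AKI") {
  stages <- if (is.data.frame(episodes)) episodes$stage else as.integer(episodes)
  stopifnot(all(stages %in% 0:3))
  if (length(stages) > cohort_n)
    stop("more episodes than admissions in the cohort", call. = FALSE)
  counts <- tabulate(stages + 1L, nbins = 4L)
  counts[1L] <- counts[1L] + (cohort_n - length(stages))
  counts <- c(counts, sum(counts[2:4]))
  ci <- t(vapply(counts, binomial_ci, numeric(2), n = cohort_n))
  out <- data.frame(
    system = system,
    stage = c("0", "1", "2", "3", "total"),
    count = counts,
    pct = round_half_up(100 * counts / cohort_n, 1),
    ci_lower = round_half_up(ci[, 1], 1),
    ci_upper = round_half_up(ci[, 2], 1),
    stringsAsFactors = FALSE
  )
  attr(out, "cohort_n") <- cohort_n
  class(out) <- c("stage_table", "data.frame")
  out
}

#' Per-stage dichotomous outcome table (mortality, critical care)
#'
#' Counts and percentages of an outcome within each AKI stage, with exact
#' binomial confidence intervals; denominators are stage sizes.
#'
#' @param stages Integer vector of stages 0-3, one per admission.
#' @param outcome Logical vector, same length.
#' @param system Label.
#' @return Data frame of class `"stage_table"` with rows `0`-`3`:
#'   `n`, `events`, `pct`, `ci_lower`, `ci_upper`.
#' @export
stage_outcome_table <- function(stages, outcome, system = "AKI") {
  stopifnot(length(stages) == length(outcome), all(stages %in% 0:3))
  rows <- lapply(0:3, function(s) {
    idx <- stages == s
    n <- sum(idx); ev <- sum(outcome[idx])
    ci <- if (n > 0) binomial_ci(ev, n) else c(NA_real_, NA_real_)
    data.frame(system = system, stage = as.character(s), n = n, events = ev,
               pct = if (n > 0) round_half_up(100 * ev / n, 1) else NA_real_,
               ci_lower = round_half_up(ci[1], 1),
               ci_upper = round_half_up(ci[2], 1))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stage_table", "data.frame")
  out
}
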
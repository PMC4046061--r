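#' Univariate, multivariate and stepwise logistic risk-factor analysis
#'
#' Fits maximum-likelihood logistic regressions of AKI status on candidate
#' risk factors: one univariate model per factor, the full multivariate
#' model, and a backward-eliminated model (AIC by default, BIC available).
#' Odds ratios, Wald 95 per cent confidence intervals and p-values are
#' reported per predictor.  Predictors whose fit shows signs of complete
#' separation are flagged non-estimable rather than reported with
#' runaway estimates.
#'
#' @param cohort Admission data frame containing the factor columns.
#' @param aki Logical vector (AKI by any criterion), one per cohort row.
#' @param factors Character vector of column names; logical/binary or
#'   continuous (e.g. `age`).
#' @param criterion `"AIC"` or `"BIC"` penalty for backward elimination.
#' @param level Confidence level.
#' @return List of class `"risk_factor_analysis"`: `univariate` (data
#'   frame), `multivariate` (data frame), `stepwise` (data frame of
#'   retained terms), `full_model` and `stepwise_model` (`glm` objects).
#' @export
risk_factor_analysis <- function(cohort, aki, factors,
                                 criterion = c("AIC", "BIC"), level = 0.95) {
  criterion <- match.arg(criterion)
  stopifnot(length(aki) == nrow(cohort))
  missing_cols <- setdiff(factors, names(cohort))
  if (length(missing_cols))
    stop("factor column(s) not in cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dat <- cohort[, factors, drop = FALSE]
  dat[] <- lapply(dat, function(x) if (is.logical(x)) as.numeric(x) else x)
  dat$.aki <- as.numeric(aki)

  z <- stats::qnorm(1 - (1 - level) / 2)
  tidy_fit <- function(fit, terms) {
    cf <- summary(fit)$coefficients
    rows <- lapply(terms, function(tm) {
      if (!tm %in% rownames(cf)) {
        return(data.frame(term = tm, or = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, p = NA_real_,
                          estimable = FALSE))
      }
      b <- cf[tm, "Estimate"]; se <- cf[tm, "Std. Error"]
      # Huge SE on the logit scale is the glm signature of separation /
      # empty cells.
      ok <- is.finite(se) && se < 10
      data.frame(term = tm,
                 or = if (ok) exp(b) else NA_real_,
                 ci_lower = if (ok) exp(b - z * se) else NA_real_,
                 ci_upper = if (ok) exp(b + z * se) else NA_real_,
                 p = if (ok) cf[tm, "Pr(>|z|)"] else NA_real_,
                 estimable = ok)
    })
    do.call(rbind, rows)
  }

  uni <- do.call(rbind, lapply(factors, function(f) {
    fit <- stats::glm(stats::reformulate(f, ".aki"), family = stats::binomial(),
                      data = dat)
    tidy_fit(fit, f)
  }))

  full <- stats::glm(stats::reformulate(factors, ".aki"),
                     family = stats::binomial(), data = dat)
  multi <- tidy_fit(full, factors)

  k_pen <- if (criterion == "AIC") 2 else log(nrow(dat))
  step_fit <- stats::step(full, direction = "backward", k = k_pen, trace = 0)
  kept <- attr(stats::terms(step_fit), "term.labels")
  stepwise <- if (length(kept)) tidy_fit(step_fit, kept) else
    data.frame(term = character(), or = numeric(), ci_lower = numeric(),
               ci_upper = numeric(), p = numeric(), estimable = logical())

  structure(list(univariate = uni, multivariate = multi, stepwise = stepwise,
                 full_model = full, stepwise_model = step_fit,
                 criterion = criterion),
            class = "risk_factor_analysis")
}

#' @export
print.risk_factor_analysis <- function(x, digits = 3, ...) {
  cat("Multivariate logistic model (full):\n")
  df <- x$multivariate
  df[c("or", "ci_lower", "ci_upper")] <-
    lapply(df[c("or", "ci_lower", "ci_upper")], round, digits)
  df$p <- signif(df$p, 2)
  print(df[c("term", "or", "ci_lower", "ci_upper", "p")], row.names = FALSE)
  cat(sprintf("\nBackward elimination (%s) retained: %s\n", x$criterion,
              if (nrow(x$stepwise)) paste(x$stepwise$term, collapse = ", ")
              else "(intercept only)"))
  invisible(x)
}
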
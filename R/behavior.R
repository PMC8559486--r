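#' Composite repetition score
#'
#' Normalises each instrument by its scale maximum (10 for the WAB-R
#' repetition subscore role, 175 for the PRT role) and averages the two
#' percentages: `(score_a/10 + score_b/175) / 2`. The composite is
#' affine and monotone nondecreasing in each argument, so the composite
#' of cohort means equals the cohort mean composite.
#' @param score_a score on the 0-10 scale.
#' @param score_b score on the 0-175 scale.
#' @return composite in `[0, 1]`. Vectorised.
#' @export
composite_repetition <- function(score_a, score_b) {
  if (any(score_a < 0 | score_a > 10))
    stopf("score_a outside its 0-10 scale")
  if (any(score_b < 0 | score_b > 175))
    stopf("score_b outside its 0-175 scale")
  (score_a / 10 + score_b / 175) / 2
}

#' Adjust the composite for age and months post-stroke
#'
#' Ordinary least squares of the composite on an intercept, age and
#' months post-stroke; the residuals (mean zero) are the adjusted
#' outcome used by all downstream modelling. Coefficients, multiple
#' R-squared and the overall F statistic are reported.
#' @param composite numeric outcome vector.
#' @param age,months nuisance covariates, same length (>= 4).
#' @return list of class `adjustment_model`: `intercept`, `beta_age`,
#'   `beta_months`, `r_squared`, `f_statistic`, `df` (c(2, n-3)),
#'   `p_value`, `residuals`.
#' @export
adjust_covariates <- function(composite, age, months) {
  n <- length(composite)
  if (length(age) != n || length(months) != n) stopf("length mismatch")
  if (n < 4) stopf("need at least 4 subjects")
  fit <- stats::lm(composite ~ age + months)
  if (fit$rank < 3) stopf("rank-deficient design: covariates collinear")
  sm <- summary(fit)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    beta_age = unname(stats::coef(fit)["age"]),
    beta_months = unname(stats::coef(fit)["months"]),
    r_squared = sm$r.squared,
    f_statistic = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)),
    residuals = unname(stats::residuals(fit))),
    class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf(
    "covariate adjustment: beta_age = %.3g, beta_months = %.3g, R^2 = %.4f, F(%d, %d) = %.3f (p = %.4g)\n",
    x$beta_age, x$beta_months, x$r_squared, x$df[1], x$df[2],
    x$f_statistic, x$p_value))
  invisible(x)
}

#' Correlation between the two repetition instruments
#'
#' Pearson correlation between the raw instrument scores; reported for
#' descriptive purposes (the composite is formed regardless).
#' @param score_a,score_b numeric vectors of length >= 3.
#' @return Pearson correlation.
#' @export
intertest_correlation <- function(score_a, score_b) {
  if (length(score_a) < 3) stopf("need at least 3 subjects")
  if (stats::sd(score_a) == 0 || stats::sd(score_b) == 0)
    stopf("zero-variance scores")
  stats::cor(score_a, score_b)
}

#' Score a cohort's behaviour table
#'
#' Convenience wrapper: computes the composite from the raw instrument
#' scores and adjusts it for age and months post-stroke.
#' @param bundle a `cohort_bundle` (or any list with `behavior_raw` and
#'   `covariates` data frames).
#' @return list with `composite`, `adjusted` (the residual outcome),
#'   `model` (the `adjustment_model`), `intertest_r`.
#' @export
score_behavior <- function(bundle) {
  b <- bundle$behavior_raw; cv <- bundle$covariates
  comp <- composite_repetition(b$score_a, b$score_b)
  am <- adjust_covariates(comp, cv$age, cv$months_post)
  list(composite = stats::setNames(comp, b$subject_id),
       adjusted = stats::setNames(am$residuals, b$subject_id),
       model = am,
       intertest_r = intertest_correlation(b$score_a, b$score_b))
}
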
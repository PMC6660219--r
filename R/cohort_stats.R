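#' Simple linear regression with slope inference
#'
#' Ordinary least squares of y on x with the two quantities the cohort
#' analyses report: the slope's 95% confidence interval and two-sided
#' p-value from the t distribution with n - 2 df, plus r-squared.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @param conf_level Confidence level for the slope interval.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `ci_lower`, `ci_upper`, `p_value`, `r_squared`, `n`.
#' @examples
#' ols_fit(1:10, 2 * (1:10) + 1)
#' @export
ols_fit <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in regression input")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = conf_level)
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 ci_lower = ci[1], ci_upper = ci[2],
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 conf_level = conf_level,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> slope %.4g (%.0f%% CI %.4g to %.4g), p = %.3g, r^2 = %.3f, n = %d\n",
    x$slope, 100 * x$conf_level, x$ci_lower, x$ci_upper,
    x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Column-wise summary of a cohort table
#'
#' Mean, min, max and SD of every numeric column of a per-eye cohort table.
#'
#' @param cohort Non-empty data frame of per-eye records.
#' @param columns Optional character vector restricting the summary.
#' @return Data frame with one row per summarised column. With a single-row
#'   cohort the SD is `NA` (flagged, not an error).
#' @export
cohort_summary <- function(cohort, columns = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort table is empty")
  num <- vapply(cohort, is.numeric, logical(1))
  cols <- names(cohort)[num]
  if (!is.null(columns)) {
    miss <- setdiff(columns, cols)
    if (length(miss)) stop("not numeric or absent: ", paste(miss, collapse = ", "))
    cols <- columns
  }
  data.frame(
    column = cols,
    mean = vapply(cols, function(cl) mean(cohort[[cl]]), numeric(1)),
    min = vapply(cols, function(cl) min(cohort[[cl]]), numeric(1)),
    max = vapply(cols, function(cl) max(cohort[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl)
      if (nrow(cohort) > 1) stats::sd(cohort[[cl]]) else NA_real_, numeric(1)),
    n = nrow(cohort),
    row.names = NULL)
}

# the four headline density-vs-axial-length regressions
.headline_regressions <- list(
  peak_ang = c("axial_length_mm", "peak_density_deg2"),
  peak_lin = c("axial_length_mm", "peak_density_mm2"),
  prl_ang = c("axial_length_mm", "prl_density_deg2"),
  prl_lin = c("axial_length_mm", "prl_density_mm2"))

#' Headline regressions of cone density on axial length
#'
#' Runs the four density-vs-axial-length regressions (peak and PRL, angular
#' and linear units) on a cohort table in the packaged fixture schema.
#'
#' @param cohort Cohort data frame.
#' @return Named list of [ols_fit()] results.
#' @export
cohort_regressions <- function(cohort) {
  lapply(.headline_regressions, function(cl) {
    miss <- setdiff(cl, names(cohort))
    if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
    ols_fit(cohort[[cl[1]]], cohort[[cl[2]]])
  })
}

#' One-eye-per-subject sensitivity analysis
#'
#' Some subjects contribute both eyes, which the headline analyses pool as
#' independent observations. This guard reruns the four headline
#' regressions on a single eye per subject and reports whether slope signs
#' and significance survive.
#'
#' @param cohort Cohort data frame with `subject` and `eye` columns.
#' @param selector `"right"`/`"left"` prefer that eye when both are present,
#'   `"first"` keeps the first listed eye, `"random"` draws one eye per
#'   subject (seeded).
#' @param seed Integer seed for `selector = "random"`.
#' @return List with `n`, the selected `cohort`, and `regressions` (named
#'   list of `regression_result`).
#' @export
one_eye_sensitivity <- function(cohort,
                                selector = c("right", "left", "first", "random"),
                                seed = NULL) {
  selector <- match.arg(selector)
  if (!all(c("subject", "eye") %in% names(cohort)))
    stop("cohort lacks subject/eye columns")
  if (selector == "random" && !is.null(seed)) set.seed(seed)
  pick <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$subject),
                        function(idx) {
    if (length(idx) == 1) return(idx)
    switch(selector,
           right = idx[match("R", cohort$eye[idx], nomatch = 1)],
           left = idx[match("L", cohort$eye[idx], nomatch = 1)],
           first = idx[1],
           random = idx[sample.int(length(idx), 1)])
  }))
  sub <- cohort[sort(pick), , drop = FALSE]
  list(n = nrow(sub), cohort = sub, regressions = cohort_regressions(sub))
}

#' Sample size for detecting a regression slope
#'
#' Normal-approximation sample size for testing a simple-regression slope
#' (the Dupont-Plummer formulation): n = (z_{1-alpha/2} + z_{power})^2 *
#' sd_errors^2 / (slope^2 * sd_x^2).
#'
#' @param slope Anticipated slope (response units per predictor unit).
#' @param sd_errors Residual standard deviation of the response.
#' @param sd_x Standard deviation of the predictor.
#' @param alpha Two-sided type-I error probability.
#' @param power Target power.
#' @return List with `n_exact` and `n` (rounded up to the next integer).
#' @examples
#' sample_size_regression(531, 1377, 1.65)
#' @export
sample_size_regression <- function(slope, sd_errors, sd_x,
                                   alpha = 0.05, power = 0.95) {
  if (any(c(sd_errors, sd_x) <= 0)) stop("SDs must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  if (slope == 0) stop("zero slope implies an infinite sample size")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_exact <- z^2 * sd_errors^2 / (slope^2 * sd_x^2)
  list(n_exact = n_exact, n = ceiling(n_exact))
}
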
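# Cohort-level statistics: paired t-tests on per-patient percentage
# differences, Bonferroni correction and summary tables. The paired test on
# raw values coincides with a one-sample t on the differences.

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y` and the n-1 sd
#' denominator; two-sided p from the Student t distribution with `n - 1`
#' degrees of freedom. Zero-variance pairs raise an error rather than
#' returning a silent NaN.
#'
#' @param x,y equal-length numeric vectors paired by patient (n >= 2).
#' @return one-row tibble: `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired (equal length).")
  n <- length(x)
  if (n < 2) abort("need at least two pairs.")
  d <- x - y
  s <- sd(d)
  if (s == 0) abort("degenerate pairs: all differences identical (zero variance).")
  t_stat <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(t = t_stat, df = df, p = p)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level in (0, 1); default 0.05.
#' @param n_tests number of tests; default 8 (four parameters, two contour
#'   methods).
#' @return corrected per-test alpha.
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests = 8) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Summarize per-patient percentage differences
#'
#' @param values numeric vector of per-patient percentages (n >= 2).
#' @return one-row tibble: `n`, `mean`, `se` (sd / sqrt(n)), `min`, `max`.
#' @export
summarize_differences <- function(values) {
  n <- length(values)
  if (n < 2) abort("need at least two values to summarize.")
  tibble::tibble(n = n, mean = mean(values), se = sd(values) / sqrt(n),
                 min = min(values), max = max(values))
}

#' Cohort summary of one parameter
#'
#' Combines [summarize_differences()] with a paired t-test of the CTACstd
#' against the CTACcba values and a significance flag at the corrected
#' alpha.
#'
#' @param parameter name of the parameter.
#' @param method contour method label.
#' @param x_std,x_cba paired per-patient values.
#' @param alpha_corrected per-test significance level.
#' @return one-row tibble.
#' @export
cohort_summary <- function(parameter, method, x_std, x_cba,
                           alpha_corrected = bonferroni_alpha()) {
  pct <- percent_difference(x_std, x_cba)
  s <- summarize_differences(pct)
  tt <- tryCatch(paired_t_test(x_std, x_cba),
                 error = function(e) tibble::tibble(t = NA_real_,
                                                    df = length(x_std) - 1,
                                                    p = NA_real_))
  tibble::tibble(parameter = parameter, method = method, n = s$n,
                 mean_pct = s$mean, se_pct = s$se, min_pct = s$min,
                 max_pct = s$max, t = tt$t, df = tt$df, p = tt$p,
                 alpha_corrected = alpha_corrected,
                 significant = !is.na(tt$p) & tt$p < alpha_corrected)
}
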
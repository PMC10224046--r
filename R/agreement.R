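# Agreement statistics between ECG- and SCG-derived inter-beat intervals:
# ordinary least-squares regression, Pearson correlation, and Bland-Altman
# bias / limits-of-agreement analysis (differences oriented SCG - ECG,
# limits at bias +/- 1.96 * SD of the differences, bias significance by a
# two-sided one-sample t-test).

#' Regression and correlation of SCG on ECG intervals
#'
#' Ordinary least squares of `scg_ibi` on `ecg_ibi`; `r_squared` is the
#' squared Pearson correlation.
#'
#' @param pairs [ibi_pairs()] object (n >= 3, ECG intervals not constant).
#' @return list with `slope`, `intercept_ms`, `r_squared`.
#' @export
regress_correlate <- function(pairs) {
  n <- pairs$n
  if (n < 3)
    scg_stop("regression needs at least 3 interval pairs",
             "scg_insufficient_data_error")
  x <- pairs$ecg_ibi_ms
  y <- pairs$scg_ibi_ms
  if (stats::sd(x) == 0)
    scg_stop("ECG intervals are constant; regression degenerate",
             "scg_degenerate_error")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept_ms = unname(stats::coef(fit)[1]),
       r_squared = r^2)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = scg - ecg` (ms): bias is `mean(d)`, the
#' limits-of-agreement half-width is `1.96 * sd(d)` (sample SD, `n - 1`
#' denominator), and the bias p-value comes from a two-sided one-sample
#' t-test of `d` against zero (`NA` when the differences are constant).
#' Regression fields are filled via [regress_correlate()] when possible.
#'
#' @param pairs [ibi_pairs()] object (n >= 3).
#' @return object of class `scg_agreement`: `slope`, `intercept_ms`,
#'   `r_squared`, `bias_ms`, `loa_halfwidth_ms`, `bias_p_value`, `n`.
#' @export
bland_altman <- function(pairs) {
  n <- pairs$n
  if (n < 3)
    scg_stop("Bland-Altman needs at least 3 interval pairs",
             "scg_insufficient_data_error")
  d <- pairs$scg_ibi_ms - pairs$ecg_ibi_ms
  bias <- mean(d)
  sdd <- stats::sd(d)
  p <- if (sdd > 0) stats::t.test(d)$p.value else NA_real_
  reg <- tryCatch(regress_correlate(pairs), scg_error = function(e)
    list(slope = NA_real_, intercept_ms = NA_real_, r_squared = NA_real_))
  structure(
    list(slope = reg$slope, intercept_ms = reg$intercept_ms,
         r_squared = reg$r_squared, bias_ms = bias,
         loa_halfwidth_ms = 1.96 * sdd, bias_p_value = p, n = n),
    class = "scg_agreement"
  )
}

#' @export
print.scg_agreement <- function(x, ...) {
  cat(sprintf("<scg_agreement: n=%d | slope %.3f, intercept %.2f ms, R^2 %.4f | bias %+.2f ms (p=%.3g), LoA +/- %.1f ms>\n",
              x$n, x$slope, x$intercept_ms, x$r_squared, x$bias_ms,
              x$bias_p_value, x$loa_halfwidth_ms))
  invisible(x)
}
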
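#' Estimate the period from a periodogram
#'
#' For the chi-square methods the estimate is the test period with the
#' smallest p-value (largest `-log10 p` — p-values, not raw statistics, are
#' compared because the degrees of freedom change with the test period); for
#' the spectral methods it is the test period with the largest power. Ties
#' resolve deterministically to the smallest test period. If every score is
#' equal (no information), the smallest test period is returned with a
#' warning.
#'
#' @param pg A periodogram, from [compute_csp()],
#'   [lomb_scargle_periodogram()] or [fft_periodogram()].
#' @param true_period_h Optional true period; when given, the signed error
#'   `estimated - true` is reported (negative = underestimation).
#' @return A one-row tibble: `method`, `estimated_period_h`, and (when
#'   `true_period_h` is supplied) `true_period_h` and `error_h`.
#' @examples
#' tc <- simulate_timecourse(period_h = 25, amplitude = 2, length_h = 72, seed = 3)
#' estimate_period(compute_csp(tc, "greedy"), true_period_h = 25)
#' @export
estimate_period <- function(pg, true_period_h = NULL) {
  if (!inherits(pg, "periodogram") || nrow(pg) == 0L) {
    abort("`pg` must be a nonempty periodogram.")
  }
  score <- if (pg$method[1L] %in% csp_methods) pg$neg_log10_p else pg$statistic
  if (length(unique(score)) == 1L) {
    warn("all periodogram scores are equal; returning the smallest test period")
  }
  est <- pg$test_period_h[which.max(score)]
  out <- tibble(method = pg$method[1L], estimated_period_h = est)
  if (!is.null(true_period_h)) {
    out$true_period_h <- true_period_h
    out$error_h <- est - true_period_h
  }
  out
}

#' Summarize a set of signed period-estimation errors
#'
#' @param errors Numeric vector of signed errors (`estimated - true`, hours);
#'   `NA`s (failed replicates) are dropped.
#' @return A one-row tibble: `n`, `mean_error_h`, `sd_error_h` (n-1
#'   denominator), `mean_abs_error_h`, `median_error_h`, and the 5th/95th
#'   percentiles `pct5_h`/`pct95_h` (linear interpolation between order
#'   statistics).
#' @export
summarize_errors <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (length(errors) == 0L) abort("`errors` must contain at least one value.")
  q <- quantile(errors, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  tibble(
    n = length(errors),
    mean_error_h = mean(errors),
    sd_error_h = if (length(errors) > 1L) sd(errors) else NA_real_,
    mean_abs_error_h = mean(abs(errors)),
    median_error_h = q[2L],
    pct5_h = q[1L],
    pct95_h = q[3L]
  )
}

# Dispatch a method tag to its periodogram function.
periodogram_for <- function(tc, method, pmin_h, pmax_h) {
  switch(method,
    standard_csp = compute_csp(tc, "standard", pmin_h, pmax_h),
    conservative_csp = compute_csp(tc, "conservative", pmin_h, pmax_h),
    greedy_csp = compute_csp(tc, "greedy", pmin_h, pmax_h),
    lomb_scargle = lomb_scargle_periodogram(tc, pmin_h, pmax_h),
    fft = fft_periodogram(tc, pmin_h, pmax_h),
    abort(sprintf("unknown method: %s", method))
  )
}
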
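#' Lomb-Scargle periodogram
#'
#' Classical normalized Lomb-Scargle power of a mean-subtracted series, in the
#' phase-offset (tau) form, evaluated on an oversampled frequency grid
#' `f_j = j / (oversampling * T)` with `T` the total duration; only
#' frequencies whose period falls in `[pmin_h, pmax_h]` are kept. With the
#' classical normalization (by the population variance of the series) a pure
#' noiseless sinusoid peaks at a power of about `n / 2`. Oversampling refines
#' peak localization without changing spectral resolution: near a period `P`
#' the grid spacing is roughly `P^2 / (oversampling * T)` hours.
#'
#' Only the peak location feeds period estimation downstream, so the choice of
#' normalization is inconsequential there.
#'
#' @inheritParams write_timecourse_csv
#' @param pmin_h,pmax_h Period range in hours.
#' @param oversampling Frequency oversampling factor (>= 1, default 100).
#' @return A periodogram tibble with `method = "lomb_scargle"`; the `df`,
#'   `neg_log10_p`, `K`, `D` columns are `NA`.
#' @examples
#' tc <- simulate_timecourse(period_h = 24, amplitude = 2, length_h = 72, seed = 1)
#' glance(lomb_scargle_periodogram(tc))
#' @export
lomb_scargle_periodogram <- function(tc, pmin_h = 18, pmax_h = 30,
                                     oversampling = 100) {
  parts <- tc_assert(tc)
  spectral_check(parts, pmin_h, pmax_h, oversampling)
  t <- (seq_len(parts$n) - 1) * parts$delta
  y <- parts$values - mean(parts$values)
  T_total <- parts$n * parts$delta

  j_lo <- max(1L, ceiling_tol(oversampling * T_total / pmax_h))
  j_hi <- floor_tol(oversampling * T_total / pmin_h)
  if (j_hi < j_lo) abort("empty frequency grid in [pmin_h, pmax_h]")
  freq <- (j_lo:j_hi) / (oversampling * T_total)
  omega <- 2 * pi * freq

  var_pop <- sum(y^2) / parts$n
  power <- vapply(omega, function(w) {
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2)) / (2 * var_pop)
  }, numeric(1))

  ord <- order(1 / freq)
  new_periodogram(
    test_period_h = (1 / freq)[ord],
    statistic = power[ord],
    method = "lomb_scargle"
  )
}

#' Zero-padded FFT periodogram
#'
#' Subtracts the mean, appends zeros until the series is `padding` times its
#' original length, computes the discrete power spectrum with [stats::fft()],
#' and keeps the bins whose period lies in `[pmin_h, pmax_h]`. Padding
#' interpolates the spectrum onto a finer frequency grid (bin spacing near a
#' period `P` is roughly `P^2 / (padding * T)` hours) without adding
#' resolution; the estimate is the raw argmax bin, with no further peak
#' interpolation.
#'
#' @inheritParams lomb_scargle_periodogram
#' @param padding Zero-padding factor (>= 1, default 100).
#' @return A periodogram tibble with `method = "fft"`.
#' @export
fft_periodogram <- function(tc, pmin_h = 18, pmax_h = 30, padding = 100) {
  parts <- tc_assert(tc)
  spectral_check(parts, pmin_h, pmax_h, padding)
  y <- parts$values - mean(parts$values)
  m <- as.integer(round(padding)) * parts$n
  z <- fft(c(y, rep.int(0, m - parts$n)))
  T_padded <- m * parts$delta

  k_lo <- max(1L, ceiling_tol(T_padded / pmax_h))
  k_hi <- min(m %/% 2L, floor_tol(T_padded / pmin_h))
  if (k_hi < k_lo) abort("empty frequency grid in [pmin_h, pmax_h]")
  k <- k_lo:k_hi
  power <- Mod(z[k + 1L])^2 / parts$n
  period <- T_padded / k

  ord <- order(period)
  new_periodogram(
    test_period_h = period[ord],
    statistic = power[ord],
    method = "fft"
  )
}

spectral_check <- function(parts, pmin_h, pmax_h, factor) {
  if (parts$n < 4L) abort("spectral methods need at least 4 points.")
  if (pmin_h >= pmax_h) abort("`pmin_h` must be smaller than `pmax_h`.")
  if (factor < 1) abort("oversampling/padding factor must be >= 1.")
  if (stats::var(parts$values) == 0) {
    abort("degenerate time-course: constant values")
  }
  invisible(TRUE)
}
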
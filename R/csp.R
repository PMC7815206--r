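#' Grid layout of a chi-square periodogram at one test period
#'
#' For a series of `n` points and a test period of `p_samples` samples, the
#' chi-square periodogram folds the series row-major into `p_samples` columns
#' (point `i`, 0-based, goes to column `i mod p_samples`). The three variants
#' differ in how many rows `K` each column gets and how many trailing points
#' `D` are omitted:
#'
#' * `standard`: `K = floor(n / p_samples)` complete rows; the trailing
#'   `D = n - K * p_samples` points are dropped. `K` changes abruptly across
#'   test periods, which is the source of the standard method's
#'   discontinuities.
#' * `conservative`: `K = floor(n / pmax_samples)`, the minimum standard `K`
#'   over the scanned range, held fixed at every test period; often discards
#'   much of the series.
#' * `greedy`: every point is used (`D = 0`); the first `n mod p_samples`
#'   columns receive one extra point and `K = n / p_samples` is the (possibly
#'   fractional) mean number of rows per column.
#'
#' @param n Number of time-points.
#' @param p_samples Test period, in samples (1 <= `p_samples` <= `n`).
#' @param variant `"standard"`, `"conservative"` or `"greedy"`.
#' @param pmax_samples Largest test period of the scan, in samples; required
#'   for the conservative variant.
#' @return A list with elements `p_samples`, `K`, `D`, `column_counts`
#'   (points per column), `included` (points used) and `variant`.
#' @examples
#' csp_layout(680, 226, "standard") # K = 3, D = 2
#' csp_layout(7, 2, "greedy")       # K = 3.5, columns of 4 and 3
#' @export
csp_layout <- function(n, p_samples, variant = c("standard", "conservative", "greedy"),
                       pmax_samples = NULL) {
  variant <- match.arg(variant)
  n <- as.integer(n)
  p_samples <- as.integer(p_samples)
  if (p_samples < 1L || p_samples > n) {
    abort("`p_samples` must satisfy 1 <= p_samples <= n.")
  }
  if (variant == "conservative") {
    if (is.null(pmax_samples)) abort("`pmax_samples` is required for the conservative variant.")
    pmax_samples <- as.integer(pmax_samples)
    if (p_samples > pmax_samples) abort("`p_samples` must not exceed `pmax_samples`.")
  }
  switch(variant,
    standard = {
      K <- n %/% p_samples
      if (K < 1L) abort("time-course shorter than test period range")
      list(p_samples = p_samples, K = as.numeric(K), D = n - K * p_samples,
           column_counts = rep.int(K, p_samples), included = K * p_samples,
           variant = variant)
    },
    conservative = {
      K <- n %/% pmax_samples
      if (K < 1L) abort("time-course shorter than test period range")
      list(p_samples = p_samples, K = as.numeric(K), D = n - K * p_samples,
           column_counts = rep.int(K, p_samples), included = K * p_samples,
           variant = variant)
    },
    greedy = {
      K0 <- n %/% p_samples
      r <- n %% p_samples
      counts <- rep.int(K0, p_samples)
      if (r > 0L) counts[seq_len(r)] <- K0 + 1L
      list(p_samples = p_samples, K = n / p_samples, D = 0L,
           column_counts = counts, included = n, variant = variant)
    }
  )
}

# Column means of the row-major fold. The included prefix is padded with NA
# to a full rectangle so one colMeans call covers integer and fractional K.
csp_column_means <- function(values, layout) {
  x <- values[seq_len(layout$included)]
  p <- layout$p_samples
  nrow_full <- ceiling(layout$included / p)
  pad <- nrow_full * p - layout$included
  m <- matrix(c(x, rep(NA_real_, pad)), ncol = p, byrow = TRUE)
  list(x = x, means = colMeans(m, na.rm = TRUE))
}

#' Chi-square periodogram statistic at one test period
#'
#' Computes the variance-ratio statistic
#' \deqn{Q_P = \frac{K N_{inc} \sum_h (\bar X_h - \bar X)^2}
#'                  {\sum_i (X_i - \bar X)^2}}
#' where the column means \eqn{\bar X_h} average the points folded into column
#' `h`, and the grand mean and the denominator run over exactly the
#' \eqn{N_{inc}} included points of the layout. `K` is the layout's row count
#' (fractional for the greedy variant). Under the no-rhythm null, \eqn{Q_P}
#' is approximately chi-square with `p_samples - 1` degrees of freedom.
#'
#' @inheritParams write_timecourse_csv
#' @param layout A layout from [csp_layout()], built for `nrow(tc)` points.
#' @return A list with `Qp` (nonnegative) and `df` (`p_samples - 1`).
#' @export
qp_statistic <- function(tc, layout) {
  parts <- tc_assert(tc)
  if (layout$included > parts$n) {
    abort("`layout` was built for a longer time-course than `tc`.")
  }
  cm <- csp_column_means(parts$values, layout)
  xbar <- mean(cm$x)
  denom <- sum((cm$x - xbar)^2)
  if (denom <= 0) {
    abort("degenerate time-course: included points have zero variance")
  }
  Qp <- layout$K * layout$included * sum((cm$means - xbar)^2) / denom
  list(Qp = Qp, df = layout$p_samples - 1L)
}

#' Upper-tail chi-square p-value on the -log10 scale
#'
#' Evaluated in log space via `pchisq(..., log.p = TRUE)` so large statistics
#' do not underflow to p = 0.
#'
#' @param Qp Nonnegative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `-log10 P(chi^2_df >= Qp)`, nonnegative.
#' @export
qp_pvalue_neglog10 <- function(Qp, df) {
  if (any(df < 1)) abort("`df` must be >= 1.")
  -pchisq(Qp, df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Compute a chi-square periodogram
#'
#' Evaluates \eqn{Q_P} at every integer sample count `P` whose period
#' `P * sampling_interval_h` lies in `[pmin_h, pmax_h]` — one test period per
#' integer number of samples, the method's native grid (it has no analogue of
#' oversampling). For each test period the result records the statistic, its
#' degrees of freedom `P - 1`, the -log10 upper-tail p-value, and the layout's
#' `K` and `D`.
#'
#' @inheritParams write_timecourse_csv
#' @param variant Chi-square periodogram variant; see [csp_layout()].
#' @param pmin_h,pmax_h Test-period range in hours (default 18–30, the
#'   conventional circadian scan).
#' @return A periodogram tibble (see [tidy.periodogram()]) with
#'   `method = "<variant>_csp"`.
#' @examples
#' tc <- simulate_timecourse(period_h = 24, amplitude = 2, length_h = 72, seed = 1)
#' pg <- compute_csp(tc, "standard")
#' glance(pg)
#' @export
compute_csp <- function(tc, variant = c("standard", "conservative", "greedy"),
                        pmin_h = 18, pmax_h = 30) {
  variant <- match.arg(variant)
  parts <- tc_assert(tc)
  if (pmin_h >= pmax_h) abort("`pmin_h` must be smaller than `pmax_h`.")
  p_lo <- max(2L, ceiling_tol(pmin_h / parts$delta))
  p_hi <- floor_tol(pmax_h / parts$delta)
  if (p_hi < p_lo) abort("empty test-period grid in [pmin_h, pmax_h]")
  if (p_hi > parts$n) {
    abort("time-course shorter than test period range")
  }
  p_grid <- p_lo:p_hi

  rows <- purrr::map(p_grid, function(p) {
    layout <- csp_layout(parts$n, p, variant, pmax_samples = p_hi)
    st <- qp_statistic(tc, layout)
    list(Qp = st$Qp, df = st$df, K = layout$K, D = layout$D)
  })
  Qp <- purrr::map_dbl(rows, "Qp")
  df <- purrr::map_int(rows, "df")
  new_periodogram(
    test_period_h = p_grid * parts$delta,
    statistic = Qp,
    method = paste0(variant, "_csp"),
    df = df,
    neg_log10_p = qp_pvalue_neglog10(Qp, df),
    K = purrr::map_dbl(rows, "K"),
    D = purrr::map_int(rows, "D")
  )
}

#' Locate the K change points of the standard chi-square periodogram
#'
#' The standard variant's row count `K = floor(n / P)` drops as the test
#' period `P` grows; every drop produces a discontinuity in the periodogram.
#' This scans the integer test-period grid and reports each `P` at which
#' `floor(n / P) < floor(n / (P - 1))`, giving the last test period before the
#' drop and the row counts on both sides. The change points are a pure
#' arithmetic consequence of `n`, independent of the data values.
#'
#' @param n Number of time-points.
#' @param pmin_samples,pmax_samples Test-period scan range, in samples.
#' @return A tibble with columns `p_before_samples` (last test period before
#'   the drop), `K_before` and `K_after`, ordered by test period.
#' @examples
#' find_k_discontinuities(680, 180, 300) # K drops 3 -> 2 after P = 226 (22.6 h)
#' @export
find_k_discontinuities <- function(n, pmin_samples, pmax_samples) {
  n <- as.integer(n)
  pmin_samples <- as.integer(pmin_samples)
  pmax_samples <- as.integer(pmax_samples)
  if (!(pmin_samples < pmax_samples && pmax_samples <= n)) {
    abort("require pmin_samples < pmax_samples <= n.")
  }
  p <- pmin_samples:pmax_samples
  K <- n %/% p
  drop_at <- which(diff(K) < 0L)  # K[drop_at] > K[drop_at + 1]
  tibble(
    p_before_samples = p[drop_at],
    K_before = K[drop_at],
    K_after = K[drop_at + 1L]
  )
}

#' Largest discontinuity of the standard chi-square periodogram
#'
#' Among the K change points in the scanned range, the transition to the
#' lowest row count removes the largest share of the averaging (a drop from
#' `K` to `K - 1` rows perturbs the statistic roughly in proportion to
#' `1 / K`), so it produces the largest jump in the periodogram. Returns the
#' last test period before that transition — e.g. 22.6, 24.0 and 25.3 h for
#' 68-, 72- and 76-h series sampled at 0.1 h and scanned over 18–30 h.
#'
#' @inheritParams find_k_discontinuities
#' @param sampling_interval_h Sampling interval used to convert samples to
#'   hours.
#' @return A one-row tibble: `p_before_samples`, `period_h`, `K_before`,
#'   `K_after`.
#' @export
largest_k_discontinuity <- function(n, pmin_samples, pmax_samples,
                                    sampling_interval_h = 0.1) {
  disc <- find_k_discontinuities(n, pmin_samples, pmax_samples)
  if (nrow(disc) == 0L) abort("no K change point in the scanned range.")
  row <- disc[which.min(disc$K_after), ]
  tibble(
    p_before_samples = row$p_before_samples,
    period_h = row$p_before_samples * sampling_interval_h,
    K_before = row$K_before,
    K_after = row$K_after
  )
}
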
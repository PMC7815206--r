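# Methods whose periodogram score is -log10(p); spectral methods score by power.
csp_methods <- c("standard_csp", "conservative_csp", "greedy_csp")
spectral_methods <- c("lomb_scargle", "fft")

new_periodogram <- function(test_period_h, statistic, method,
                            df = NA_integer_, neg_log10_p = NA_real_,
                            K = NA_real_, D = NA_integer_) {
  out <- tibble(
    test_period_h = test_period_h,
    statistic = statistic,
    df = as.integer(df),
    neg_log10_p = neg_log10_p,
    K = as.numeric(K),
    D = as.integer(D),
    method = method
  )
  stopifnot(!is.unsorted(out$test_period_h, strictly = TRUE))
  class(out) <- c("periodogram", class(out))
  out
}

#' @export
print.periodogram <- function(x, ...) {
  peak <- x[periodogram_peak_index(x), ]
  cat(sprintf("# Periodogram: %s, %d test periods in [%.4g, %.4g] h\n",
              x$method[1L], nrow(x), min(x$test_period_h), max(x$test_period_h)))
  cat(sprintf("# Peak at %.4g h (statistic %.4g)\n",
              peak$test_period_h, peak$statistic))
  NextMethod()
}

# Index of the peak: maximum -log10(p) for chi-square methods, maximum power
# for spectral ones; ties resolve to the smallest test period (rows are
# sorted by period, so the first maximum wins).
periodogram_peak_index <- function(pg) {
  score <- if (pg$method[1L] %in% csp_methods) pg$neg_log10_p else pg$statistic
  which.max(score)
}

#' Turn a periodogram into a plain tibble
#'
#' @param x A periodogram, as returned by [compute_csp()],
#'   [lomb_scargle_periodogram()] or [fft_periodogram()].
#' @param ... Unused.
#' @return A tibble with columns `test_period_h`, `statistic`, `df`,
#'   `neg_log10_p`, `K`, `D`, `method` (the last four are `NA` for the
#'   spectral methods).
#' @exportS3Method generics::tidy
tidy.periodogram <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "periodogram")
  as_tibble(out)
}

#' One-row summary of a periodogram
#'
#' @inheritParams tidy.periodogram
#' @return A one-row tibble: `method`, `n_periods`, `pmin_h`, `pmax_h`,
#'   `peak_period_h`, `peak_statistic`, `peak_neg_log10_p`.
#' @exportS3Method generics::glance
glance.periodogram <- function(x, ...) {
  i <- periodogram_peak_index(x)
  tibble(
    method = x$method[1L],
    n_periods = nrow(x),
    pmin_h = min(x$test_period_h),
    pmax_h = max(x$test_period_h),
    peak_period_h = x$test_period_h[i],
    peak_statistic = x$statistic[i],
    peak_neg_log10_p = x$neg_log10_p[i]
  )
}

#' Plot a periodogram
#'
#' Chi-square periodograms are drawn as -log10(p) against test period, with
#' the conventional alpha = 0.05 chi-square significance line (which varies
#' with the test period because the degrees of freedom do); spectral
#' periodograms are drawn as power against period.
#'
#' @param object A periodogram.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.periodogram <- function(object, ...) {
  is_csp <- object$method[1L] %in% csp_methods
  if (is_csp) {
    sig <- -pchisq(stats::qchisq(0.95, object$df), object$df,
                   lower.tail = FALSE, log.p = TRUE) / log(10)
    ggplot2::ggplot(object, ggplot2::aes(.data$test_period_h, .data$neg_log10_p)) +
      ggplot2::geom_line() +
      ggplot2::geom_line(ggplot2::aes(y = sig), linetype = "dashed", colour = "grey40") +
      ggplot2::labs(x = "Test period (h)", y = expression(-log[10](italic(p))),
                    title = object$method[1L])
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$test_period_h, .data$statistic)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Test period (h)", y = "Power", title = object$method[1L])
  }
}

#' Read and write periodogram CSV files
#'
#' Flat CSV with columns
#' `test_period_h,statistic,df,neg_log10_p,K,D,method`; the `df`,
#' `neg_log10_p`, `K` and `D` cells are empty for spectral methods.
#'
#' @param pg A periodogram.
#' @param path Path to a CSV file.
#' @return `write_periodogram_csv()` returns `path` invisibly;
#'   `read_periodogram_csv()` returns a periodogram.
#' @export
write_periodogram_csv <- function(pg, path) {
  readr::write_csv(tidy(pg), path, na = "")
  invisible(path)
}

#' @rdname write_periodogram_csv
#' @export
read_periodogram_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    test_period_h = readr::col_double(),
    statistic = readr::col_double(),
    df = readr::col_integer(),
    neg_log10_p = readr::col_double(),
    K = readr::col_double(),
    D = readr::col_integer(),
    method = readr::col_character()
  ))
  new_periodogram(df$test_period_h, df$statistic, df$method,
                  df = df$df, neg_log10_p = df$neg_log10_p, K = df$K, D = df$D)
}
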
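#' Construct an evenly sampled time-course
#'
#' A time-course is the universal input of this package: a tibble with columns
#' `time_h` (hours) and `value`, sampled at a constant interval. All
#' periodogram functions accept any data frame with these two columns and an
#' even time grid; `timecourse()` builds one from a value vector.
#'
#' @param values Numeric vector of measurements (length >= 2). Arbitrary units
#'   (e.g. bioluminescence) or nonnegative integer counts (e.g. wheel
#'   revolutions).
#' @param sampling_interval_h Positive sampling interval in hours.
#' @param start_time_h Time of the first point, in hours. Default 0.
#'
#' @return A tibble with columns `time_h` and `value`, where
#'   `time_h[i] = start_time_h + (i - 1) * sampling_interval_h`.
#'
#' @examples
#' tc <- timecourse(sin(2 * pi * (0:719) * 0.1 / 24), sampling_interval_h = 0.1)
#' tc_duration_h(tc)
#' @export
timecourse <- function(values, sampling_interval_h, start_time_h = 0) {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector with at least 2 points.")
  }
  if (!is.numeric(sampling_interval_h) || length(sampling_interval_h) != 1L ||
      !is.finite(sampling_interval_h) || sampling_interval_h <= 0) {
    abort("`sampling_interval_h` must be a single positive number.")
  }
  tibble(
    time_h = start_time_h + (seq_along(values) - 1) * sampling_interval_h,
    value = as.numeric(values)
  )
}

# Validate a time-course data frame and return its components.
# Enforces the even-sampling contract shared by every periodogram here: the
# chi-square grid fold is meaningless for uneven data, so uneven spacing is a
# hard error that names the first offending row.
tc_assert <- function(tc, arg = "tc", tol = 1e-6) {
  if (!is.data.frame(tc)) {
    abort(sprintf("`%s` must be a data frame with columns `time_h` and `value`.", arg))
  }
  missing_cols <- setdiff(c("time_h", "value"), names(tc))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste0("`", missing_cols, "`", collapse = ", ")))
  }
  time_h <- as.numeric(tc$time_h)
  values <- as.numeric(tc$value)
  if (length(values) < 2L) {
    abort(sprintf("`%s` must contain at least 2 rows.", arg))
  }
  if (anyNA(time_h) || anyNA(values)) {
    abort(sprintf("`%s` contains missing values.", arg))
  }
  d <- diff(time_h)
  if (any(d <= 0)) {
    abort(sprintf("`%s`: times must be strictly increasing (violated at row %d).",
                  arg, which(d <= 0)[1L] + 1L))
  }
  delta <- median(d)
  off <- which(abs(d - delta) > tol * delta)
  if (length(off) > 0L) {
    abort(sprintf(
      "`%s`: uneven sampling at row %d (spacing %.6g h vs. median %.6g h). Evenly sampled input is required.",
      arg, off[1L] + 1L, d[off[1L]], delta))
  }
  list(values = values, delta = delta, start = time_h[1L], n = length(values))
}

#' Read and write time-course CSV files
#'
#' The on-disk format is a two-column CSV with header `time_h,value`
#' (times in hours). On read, the sampling interval is inferred from the
#' median spacing unless supplied, and uneven spacing (beyond a relative
#' tolerance of 1e-6) is rejected.
#'
#' @param path Path to a CSV file.
#' @param sampling_interval_h Optional sampling interval in hours; overrides
#'   the inferred spacing and rebuilds the time axis from the first time-point.
#'
#' @return `read_timecourse_csv()` returns a time-course tibble
#'   (columns `time_h`, `value`); `write_timecourse_csv()` returns `path`
#'   invisibly.
#' @export
read_timecourse_csv <- function(path, sampling_interval_h = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    time_h = readr::col_double(),
    value = readr::col_double()
  ))
  if (anyNA(df$time_h) || anyNA(df$value)) {
    abort(sprintf("Non-numeric or missing cell while parsing %s.", path))
  }
  parts <- tc_assert(df, arg = "path")
  if (!is.null(sampling_interval_h)) {
    timecourse(parts$values, sampling_interval_h, start_time_h = parts$start)
  } else {
    tibble(time_h = as.numeric(df$time_h), value = parts$values)
  }
}

#' @param tc A time-course data frame (columns `time_h`, `value`).
#' @rdname read_timecourse_csv
#' @export
write_timecourse_csv <- function(tc, path) {
  parts <- tc_assert(tc)
  readr::write_csv(tibble(time_h = tc$time_h, value = parts$values), path)
  invisible(path)
}

#' Total duration of a time-course
#'
#' Duration counts one sampling interval per point
#' (`n * sampling_interval_h`), so a 720-point series at 0.1 h is 72 h.
#'
#' @inheritParams write_timecourse_csv
#' @return Duration in hours.
#' @export
tc_duration_h <- function(tc) {
  parts <- tc_assert(tc)
  parts$n * parts$delta
}

#' Truncate a time-course to a given length
#'
#' Keeps the first `floor(length_h / sampling_interval_h)` points (prefix
#' truncation); the start time is unchanged. Used to study how recording
#' length interacts with periodogram bias, e.g. cutting a free-running record
#' to 3, 5 or 7 "days" of 23 or 24 h.
#'
#' @inheritParams write_timecourse_csv
#' @param length_h Target length in hours; must not exceed the duration and
#'   must retain at least 2 points.
#' @return A time-course tibble with the first points of `tc`.
#' @examples
#' tc <- simulate_timecourse(period_h = 24, length_h = 168, seed = 1)
#' nrow(truncate_timecourse(tc, 69)) # 3 "23-h days" at 0.1-h sampling
#' @export
truncate_timecourse <- function(tc, length_h) {
  parts <- tc_assert(tc)
  if (!is.numeric(length_h) || length(length_h) != 1L || length_h <= 0) {
    abort("`length_h` must be a single positive number.")
  }
  n_keep <- floor_tol(length_h / parts$delta)
  if (n_keep > parts$n) {
    abort(sprintf("`length_h` (%g h) exceeds the time-course duration (%g h).",
                  length_h, parts$n * parts$delta))
  }
  if (n_keep < 2L) {
    abort("`length_h` would retain fewer than 2 points.")
  }
  tc[seq_len(n_keep), c("time_h", "value")] |> as_tibble()
}
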
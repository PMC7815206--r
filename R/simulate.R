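# cache for sawtooth normalization constants, keyed by number of terms
.beta_cache <- new.env(parent = emptyenv())

#' Normalization constant of the smooth sawtooth waveform
#'
#' The smooth sawtooth is the partial Fourier sum
#' \eqn{\sum_{k=1}^{n} \sin(2\pi k u)/k^2} rescaled to peak at 1. Its maximum
#' over one cycle, \eqn{\beta}, has no closed form; it is found numerically by
#' a dense grid search over \eqn{u \in [0, 1)} followed by local refinement
#' with [stats::optimize()] to a tolerance of 1e-8. For the default 100 terms
#' \eqn{\beta \approx 1.01495}. Values are cached per `n_terms`.
#'
#' @param n_terms Number of Fourier terms (positive integer).
#' @param grid_points Size of the initial search grid on `[0, 1)`.
#' @return The maximum of the unnormalized sawtooth sum over one cycle.
#' @examples
#' sawtooth_norm_beta(1)   # a single sine term: exactly 1
#' sawtooth_norm_beta(100)
#' @export
sawtooth_norm_beta <- function(n_terms = 100, grid_points = 1e5) {
  if (!is.numeric(n_terms) || length(n_terms) != 1L || n_terms < 1) {
    abort("`n_terms` must be a positive integer.")
  }
  n_terms <- as.integer(n_terms)
  key <- as.character(n_terms)
  cached <- .beta_cache[[key]]
  if (!is.null(cached)) return(cached)

  k <- seq_len(n_terms)
  f <- function(u) abs(colSums(sin(2 * pi * outer(k, u)) / k^2))
  u_grid <- seq(0, 1, length.out = grid_points + 1)[-(grid_points + 1)]
  vals <- f(u_grid)
  u0 <- u_grid[which.max(vals)]
  h <- 2 / grid_points
  opt <- optimize(function(u) f(u), interval = c(u0 - h, u0 + h),
                  maximum = TRUE, tol = 1e-8)
  beta <- max(opt$objective, max(vals))
  .beta_cache[[key]] <- beta
  beta
}

#' Rhythmic waveforms on [-1, 1]
#'
#' Evaluates one of three periodic waveforms at time `t` (hours) for a given
#' period \eqn{\tau}:
#' * `sine`: \eqn{\sin(2\pi t/\tau)};
#' * `smooth_sawtooth`: \eqn{(1/\beta)\sum_{k=1}^{n}\sin(2\pi k t/\tau)/k^2}
#'   with `n_terms = 100` terms and \eqn{\beta} from [sawtooth_norm_beta()],
#'   a gradual rise with a rapid fall, as in late-subjective-night-peaking
#'   rhythms;
#' * `smooth_square`: \eqn{\arctan(\sin(2\pi t/\tau)/\delta)/\arctan(1/\delta)}
#'   with \eqn{\delta = 0.2}, a squarish alternation with smooth shoulders
#'   resembling bouts of activity and rest.
#'
#' All three have range exactly \eqn{[-1, 1]}.
#'
#' @param waveform One of `"sine"`, `"smooth_sawtooth"`, `"smooth_square"`.
#' @param t Time(s) in hours (vectorized).
#' @param period_h Period \eqn{\tau} in hours (> 0).
#' @param n_terms,delta Shape parameters of the sawtooth and square waveforms.
#' @return Numeric vector of waveform values in `[-1, 1]`.
#' @export
waveform_value <- function(waveform, t, period_h, n_terms = 100, delta = 0.2) {
  waveform <- match.arg(waveform, c("sine", "smooth_sawtooth", "smooth_square"))
  if (!is.numeric(period_h) || length(period_h) != 1L || period_h <= 0) {
    abort("`period_h` must be a single positive number.")
  }
  u <- t / period_h
  switch(waveform,
    sine = sin(2 * pi * u),
    smooth_sawtooth = {
      k <- seq_len(n_terms)
      colSums(sin(2 * pi * outer(k, u)) / k^2) / sawtooth_norm_beta(n_terms)
    },
    smooth_square = atan(sin(2 * pi * u) / delta) / atan(1 / delta)
  )
}

#' Simulate a rhythmic time-course
#'
#' Generates an evenly sampled series `A * f(t - phase) + noise`, where `f` is
#' one of the waveforms of [waveform_value()]. Two noise models are available:
#'
#' * `gaussian`: i.i.d. Normal(0, `noise_sd`^2) added to the rhythm
#'   (default sd 1), for continuous measures such as bioluminescence;
#' * `poisson`: integer counts drawn with mean (and variance)
#'   `A * f(t - phase) + A + 1`, which is always >= 1, emulating activity
#'   counts such as wheel revolutions.
#'
#' With `phase_h = "random"` the phase is drawn uniformly on `[0, period_h)`,
#' so replicate batches do not share a phase. Given a `seed` the output is
#' fully deterministic; the global RNG state is left untouched.
#'
#' @param period_h True period \eqn{\tau} in hours.
#' @param amplitude Rhythm amplitude `A` (>= 0).
#' @param waveform Waveform kind; see [waveform_value()].
#' @param length_h Time-course length in hours; the series has
#'   `floor(length_h / sampling_interval_h)` points starting at t = 0.
#' @param sampling_interval_h Sampling interval in hours (default 0.1).
#' @param phase_h Phase shift in hours, or `"random"` for a uniform draw on
#'   `[0, period_h)`.
#' @param noise `"gaussian"` or `"poisson"`.
#' @param noise_sd Standard deviation of the Gaussian noise (>= 0; ignored for
#'   Poisson noise).
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used (and advanced).
#' @return A time-course tibble (columns `time_h`, `value`).
#' @examples
#' tc <- simulate_timecourse(period_h = 25, amplitude = 2, length_h = 72, seed = 7)
#' head(tc)
#' @export
simulate_timecourse <- function(period_h = 24, amplitude = 2,
                                waveform = c("sine", "smooth_sawtooth", "smooth_square"),
                                length_h = 72, sampling_interval_h = 0.1,
                                phase_h = "random",
                                noise = c("gaussian", "poisson"),
                                noise_sd = 1, seed = NULL) {
  waveform <- match.arg(waveform)
  noise <- match.arg(noise)
  if (period_h <= 0) abort("`period_h` must be positive.")
  if (amplitude < 0) abort("`amplitude` must be nonnegative.")
  if (length_h <= 0 || sampling_interval_h <= 0) {
    abort("`length_h` and `sampling_interval_h` must be positive.")
  }
  if (noise == "gaussian" && (!is.numeric(noise_sd) || noise_sd < 0)) {
    abort("`noise_sd` must be >= 0.")
  }
  n <- floor_tol(length_h / sampling_interval_h)
  if (n < 2L) abort("`length_h` must cover at least 2 sampling intervals.")
  t <- (seq_len(n) - 1) * sampling_interval_h

  draw <- function() {
    phase <- if (identical(phase_h, "random")) runif(1, 0, period_h) else {
      if (!is.numeric(phase_h) || length(phase_h) != 1L) {
        abort("`phase_h` must be a single number or \"random\".")
      }
      phase_h
    }
    f <- waveform_value(waveform, t - phase, period_h)
    if (noise == "gaussian") {
      amplitude * f + rnorm(n, 0, noise_sd)
    } else {
      as.numeric(rpois(n, amplitude * f + amplitude + 1))
    }
  }
  values <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  timecourse(values, sampling_interval_h)
}

#' Simulate a batch of replicate time-courses
#'
#' Draws `n_replicates` independent time-courses from the same design. Each
#' replicate gets its own seed from a deterministic stream split of
#' `base_seed` (a vector of replicate seeds is drawn up front), so a batch is
#' bit-reproducible and replicate `j` does not depend on how many replicates
#' precede it. Phases are independent across replicates when
#' `phase_h = "random"`.
#'
#' @inheritParams simulate_timecourse
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Integer seed for the batch.
#' @return A list of `n_replicates` time-course tibbles.
#' @export
simulate_batch <- function(n_replicates, base_seed, ...) {
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be >= 1.")
  }
  seeds <- withr::with_seed(base_seed,
                            sample.int(.Machine$integer.max, n_replicates))
  purrr::map(seeds, function(s) simulate_timecourse(..., seed = s))
}
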
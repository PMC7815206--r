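# Independent, deliberately naive oracles used to cross-check the package's
# vectorized implementations.

# Double-loop evaluation of the chi-square periodogram statistic from first
# principles: explicit grid fill, explicit column means, explicit sums.
qp_loop_oracle <- function(values, p, variant, pmax = NULL) {
  n <- length(values)
  if (variant == "standard") {
    K <- floor(n / p)
    counts <- rep(K, p)
  } else if (variant == "conservative") {
    K <- floor(n / pmax)
    counts <- rep(K, p)
  } else {
    K <- n / p
    counts <- integer(p)
    for (i in seq_len(n)) {
      h <- (i - 1) %% p + 1
      counts[h] <- counts[h] + 1
    }
  }
  n_inc <- sum(counts)
  col_sum <- numeric(p)
  col_n <- integer(p)
  x_inc <- numeric(0)
  for (i in seq_len(n_inc)) {
    h <- (i - 1) %% p + 1
    col_sum[h] <- col_sum[h] + values[i]
    col_n[h] <- col_n[h] + 1
    x_inc <- c(x_inc, values[i])
  }
  stopifnot(all(col_n == counts))
  xbar <- mean(x_inc)
  num <- 0
  for (h in seq_len(p)) {
    num <- num + (col_sum[h] / col_n[h] - xbar)^2
  }
  den <- 0
  for (i in seq_along(x_inc)) den <- den + (x_inc[i] - xbar)^2
  K * n_inc * num / den
}

# Least-squares sinusoid fit at a known period; returns amplitude and phase.
harmonic_fit <- function(time_h, values, period_h) {
  X <- cbind(1, cos(2 * pi * time_h / period_h), sin(2 * pi * time_h / period_h))
  b <- qr.solve(X, values)
  list(amplitude = sqrt(b[2]^2 + b[3]^2),
       phase_h = (atan2(b[2], b[3]) %% (2 * pi)) * period_h / (2 * pi))
}

make_sine_tc <- function(period_h = 24, length_h = 72, delta = 0.1,
                         amplitude = 2, phase_h = 0) {
  t <- (seq_len(round(length_h / delta)) - 1) * delta
  timecourse(amplitude * sin(2 * pi * (t - phase_h) / period_h), delta)
}

all_methods <- c("standard_csp", "conservative_csp", "greedy_csp",
                 "lomb_scargle", "fft")

estimate_with <- function(tc, method, pmin_h = 18, pmax_h = 30) {
  pg <- switch(method,
    standard_csp = compute_csp(tc, "standard", pmin_h, pmax_h),
    conservative_csp = compute_csp(tc, "conservative", pmin_h, pmax_h),
    greedy_csp = compute_csp(tc, "greedy", pmin_h, pmax_h),
    lomb_scargle = lomb_scargle_periodogram(tc, pmin_h, pmax_h),
    fft = fft_periodogram(tc, pmin_h, pmax_h)
  )
  estimate_period(pg)$estimated_period_h
}
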
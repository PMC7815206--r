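# rhythmogram

Period estimation for circadian and other biological rhythms from evenly
sampled time-courses (wheel-running counts, bioluminescence, body
temperature, ...), with a focus on a failure mode of the most widely used
method: the chi-square periodogram's period-dependent underestimation bias.

## The methods

For a series of `N` points and a candidate ("test") period of `P` samples,
the **chi-square periodogram** (CSP) folds the series row-major into a grid
with `P` columns and compares the variance of the column means to the total
variance:

```
Q_P = K * N_inc * sum_h (Xbar_h - Xbar)^2 / sum_i (X_i - Xbar)^2
```

where `K` is the number of rows, `N_inc` the number of points used, and the
grand mean and denominator run over those points. Under the no-rhythm null,
`Q_P` is approximately chi-square with `P - 1` degrees of freedom; the
estimated period is the test period with the smallest p-value. The package
implements three variants that differ only in the grid:

| variant | rows `K` | omitted points `D` |
|---|---|---|
| `standard` | `floor(N / P)` | `N - K * P` |
| `conservative` | `floor(N / P_max)`, fixed across the scan | `N - K * P` (large) |
| `greedy` | `N / P` (fractional; unequal columns) | 0 |

The standard variant's `K` drops abruptly at test periods of which the
recording length is a multiple. Each drop is a discontinuity in the
periodogram, and because recordings are conventionally cut to multiples of
24 h, the peak tends to *pin* to the 24.0-h test period whenever the true
period is slightly longer — a systematic underestimation that does not
shrink with more animals. `find_k_discontinuities()` locates these change
points analytically; the conservative and greedy variants remove them by
construction. Two spectral baselines — the classical **Lomb-Scargle
periodogram** (oversampling factor 100) and a **zero-padded FFT**
(padding factor 100) — are included, and on simulated data remain more
accurate than any CSP variant.

A simulator (`simulate_timecourse()`) generates rhythms with sinusoid,
smooth-sawtooth, or smooth-square waveforms, Gaussian or Poisson noise, and
random phase; `run_bias_sweep()` crosses lengths, true periods, amplitudes
and waveforms in a reproducible Monte-Carlo benchmark.

## Worked example

A synthetic 3-day activity-count recording (true period 24.5 h, Poisson
counts at 0.25-h sampling) ships with the package:

```r
library(rhythmogram)

path <- system.file("extdata", "synthetic_wheel_counts.csv", package = "rhythmogram")
tc <- read_timecourse_csv(path)

dplyr::bind_rows(
  estimate_period(compute_csp(tc, "standard"), true_period_h = 24.5),
  estimate_period(compute_csp(tc, "greedy"),   true_period_h = 24.5),
  estimate_period(lomb_scargle_periodogram(tc), true_period_h = 24.5)
)
#> # A tibble: 3 × 4
#>   method       estimated_period_h true_period_h error_h
#>   <chr>                     <dbl>         <dbl>   <dbl>
#> 1 standard_csp               23.8          24.5 -0.75
#> 2 greedy_csp                 25.2          24.5  0.75
#> 3 lomb_scargle               24.4          24.5 -0.0932
```

The standard CSP lands below 24 h: its periodogram has a discontinuity
exactly where `K` drops from 3 to 2 rows, which

```r
largest_k_discontinuity(n = 288, pmin_samples = 72, pmax_samples = 120,
                        sampling_interval_h = 0.25)
#> # A tibble: 1 × 4
#>   p_before_samples period_h K_before K_after
#>              <int>    <dbl>    <int>   <int>
#> 1               96       24        3       2
```

places at the 24.0-h test period — the recording length (72 h) divided by 3.
The greedy variant has no discontinuity but, on a series this short and
noisy, more variance than the Lomb-Scargle estimate (off by 0.09 h, about
one grid step). Periodogram objects print, `tidy()`, `glance()` and
`autoplot()`; sweeps return tibbles ready for dplyr/ggplot2.

A thin command-line interface wraps the same functions:

```sh
exec/rhythmogram estimate --input tc.csv --method greedy_csp --pmin 18 --pmax 30
exec/rhythmogram simulate --config sim.yaml --out tc.csv
exec/rhythmogram sweep --config sweep.yaml --out summaries.csv
```

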
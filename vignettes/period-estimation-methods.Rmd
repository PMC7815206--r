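---
title: "Period estimation with chi-square, Lomb-Scargle and FFT periodograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Period estimation with chi-square, Lomb-Scargle and FFT periodograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmogram)
```

## The estimation problem

Free-running circadian rhythms have periods near, but rarely exactly, 24 h.
Estimating that period from a finite recording — wheel-running counts,
bioluminescence from a clock-gene reporter, body temperature — is a routine
step in chronobiology, and differences of a few tenths of an hour between
genotypes or treatments are biologically meaningful. This package
implements the most common estimator, the chi-square periodogram (CSP), two
revisions of it that remove a structural artifact, and two spectral
baselines, together with the simulation machinery needed to measure each
method's accuracy.

All methods operate on an evenly sampled time-course: a tibble with columns
`time_h` and `value`, sampled every `Δ` hours. Even sampling is enforced at
the boundary (`read_timecourse_csv()` rejects spacings deviating more than
a relative 1e-6 from the median, naming the offending row), because the
CSP's grid fold is undefined for uneven data.

## The chi-square periodogram and its discontinuities

For a candidate period of `P` samples, the series is folded row-major into
`P` columns. With column means $\bar X_h$, grand mean $\bar X$, row count
$K$ and $N_{inc}$ included points, the statistic is

$$Q_P \;=\; \frac{K\,N_{inc}\sum_{h=1}^{P}(\bar X_h-\bar X)^2}
                {\sum_{i}(X_i-\bar X)^2},$$

approximately $\chi^2_{P-1}$ under the no-rhythm null. One detail is
genuinely ambiguous in the literature: whether the grand mean and the
denominator run over all $N$ points or only the $N_{inc}$ points that fit
the grid. We use the included points only, for internal consistency of the
variance-ratio interpretation — then the null expectation is exactly
$N_{inc}(P-1)/(N_{inc}-1)$, which the test suite verifies by simulation.
A periodogram evaluates every integer sample count whose period lies in
`[pmin_h, pmax_h]` (default 18–30 h, the conventional circadian scan); the
method has no analogue of oversampling, so the grid step is the sampling
interval. Scores are compared as $-\log_{10} p$ computed in log space
(`pchisq(..., log.p = TRUE)`), never as raw statistics, because the degrees
of freedom `P − 1` change along the scan; log-space evaluation keeps
p-values finite for arbitrarily large statistics.

The three variants differ only in the grid layout:

* **standard**: $K=\lfloor N/P\rfloor$, the trailing $D=N-KP$ points are
  dropped. $K$ jumps at every $P$ dividing into $N$ one fewer time — an
  analytic property of $N$ alone, which `find_k_discontinuities()` reports
  without touching the data. Each jump is a discontinuity in the
  periodogram; the transition to the lowest $K$ in the scan removes the
  largest fraction of averaging and is the largest one
  (`largest_k_discontinuity()`). For 68-, 72- and 76-h series at 0.1-h
  sampling these sit at 22.6, 24.0 and 25.3 h. Because the statistic drops
  sharply just *above* such a test period, true periods slightly above it
  are estimated at or just below it ("pinning"), an underestimation bias
  that no increase in sample size removes.
* **conservative**: $K=\lfloor N/P_{max}\rfloor$ held fixed across the scan.
  No discontinuities, but much of the series is discarded (e.g. 2 of 7
  complete cycles at the default scan of a 3-day recording), so the
  estimates have high variance; the statistic also depends on the chosen
  $P_{max}$, which is why the package recomputes `K` whenever `pmax_h`
  changes.
* **greedy**: every point is used; the first $N \bmod P$ columns get one
  extra row, and $K=N/P$ is fractional. Row-major assignment means exactly
  the leading columns carry the extra observation, matching sequential
  reading of the series. The prefactor uses the exact rational $N/P$.

Two fine points that the noiseless limit exposes, verified against
independent oracles in development and documented here because they bound
what the methods can do. First, the greedy statistic's $K=N/P$ prefactor
grows as $P$ decreases (about 2% per 0.5 h near 24 h on a 72-h series)
while column-mean smearing from period mismatch costs less (about 1% at
$K\approx 3$), so on a *noise-free* short series the greedy peak sits a few
grid steps below the true period; the chi-square degrees-of-freedom slope
adds a similar pull on the p-value scale. With realistic noise this
deterministic drift is a fraction of the estimator's spread, but it is why
the greedy variant's median error on 3-day series is slightly negative
(−0.2 to −0.3 h) rather than zero, and why the property tests assert exact
noiseless recovery only on long (12-cycle) series. Second, for the same
reason the standard variant's minimum-p estimate under pinning
concentrates at the discontinuity *and one grid step below it*: on 3-day
series with true periods 24.2–24.8 h the median estimate is 23.9–24.0 h,
insensitive to the truth. The tests characterize pinning that way rather
than as a point value.

## Spectral baselines

The Lomb-Scargle periodogram is the classical phase-offset ($\tau$) form on
mean-subtracted data, normalized by the population variance so a pure tone
peaks at about $N/2$. The frequency grid is $f_j = j/(\mathrm{ofac}\cdot T)$
with oversampling factor 100, restricted to periods inside the scan; near a
period $P$ the grid step is roughly $P^2/(\mathrm{ofac}\cdot T)$ hours
(0.08 h at 24 h on a 3-day series). The FFT baseline subtracts the mean,
zero-pads to 100× the series length, and takes the raw argmax bin — no
taper and no quadratic peak interpolation, since padding already refines
the grid. Oversampling and padding sharpen peak *localization* only; they
do not add resolution, and the tests check that the refined argmax never
leaves the coarse bin containing the unrefined one.

One caveat, confirmed against an independent FFT implementation: with a
rectangular window and only three cycles, interference from the
negative-frequency lobe displaces the padded spectrum's true maximum by up
to ~0.4 h from an exactly on-grid period. This is a property of the raw
padded periodogram, not an implementation artifact; it disappears by 12
cycles, where recovery is exact to one refined bin. In noisy, realistic
simulations the spectral methods are nonetheless the most accurate of the
five.

## The simulator

`simulate_timecourse()` draws
$x(t_i) = A\,f(t_i-\varphi) + \varepsilon_i$ with $t_i = i\Delta$,
$i = 0,\dots,\lfloor L/\Delta\rfloor - 1$. Defaults follow common practice
for benchmarking circadian estimators: sampling interval $\Delta = 0.1$ h,
length 72 h, amplitude 2, Gaussian noise of sd 1, phase drawn uniformly on
$[0,\tau)$ per replicate. Three unit-amplitude waveforms are available:

* `sine` — $\sin(2\pi t/\tau)$;
* `smooth_sawtooth` — $\beta^{-1}\sum_{k=1}^{100}\sin(2\pi k t/\tau)/k^2$,
  a gradual rise with a fast fall. The normalizer $\beta$ is the numerical
  maximum of the truncated sum (dense 1e5-point grid, then `optimize()` to
  1e-8, cached per term count). For 100 terms this is 1.0149868; note the
  infinite series converges to the Clausen-function maximum 1.0149416
  (Gieseking's constant), which the truncated sum slightly overshoots, so
  quoting the limit value as the normalizer leaves the waveform marginally
  outside $[-1,1]$. We normalize by the exact truncated maximum.
* `smooth_square` — $\arctan(\sin(2\pi t/\tau)/\delta)/\arctan(1/\delta)$
  with $\delta = 0.2$, bouts of activity and rest with smooth shoulders.

Poisson noise replaces the additive model by integer counts with mean (and
variance) $A f(t-\varphi) + A + 1 \ge 1$, emulating activity counts. For
the Gaussian model we add no baseline offset: every estimator here is
invariant to additive constants, so an offset would be dead weight. The
phase convention ($f(t-\varphi)$, subtracted) is likewise arbitrary and
inconsequential, since estimation is phase-invariant.

Replicate batches split the base seed into per-replicate seeds drawn up
front, so a batch is bit-reproducible, replicates are independent, and the
result does not depend on evaluation order. The simulator emulates
stationary, single-period rhythms with i.i.d. noise; it does not model
damping, period drift, baseline trends or autocorrelated noise. Passing
benchmarks here therefore speaks to estimator behavior under the stated
conditions, not to robustness against those real-data complications
(stationarity is, however, an assumption every method tested shares).

## The bias sweep

`run_bias_sweep()` crosses lengths × true periods × amplitudes × waveforms
× noise models, simulates `n_replicates` time-courses per cell (default
100), estimates the period with each requested method, and summarizes the
signed error per cell. The sign convention is `estimated − true`, so
underestimation is negative. Ties in a periodogram resolve to the smallest
test period, deterministically; an all-flat periodogram returns the
smallest test period with a warning. Summaries report mean, sd (n−1),
mean absolute error, median, and 5th/95th percentiles with linear
interpolation between order statistics (R's default quantile type 7). A
method failing on a replicate (e.g. a degenerate constant series) records
`NA` rather than aborting the sweep.

## Numerical choices

* Hour-to-sample conversions guard `floor()`/`ceiling()` with a relative
  1e-9 tolerance, since ratios like 69/0.1 fall just below their integer in
  binary floating point; truncation to a length within one sampling
  interval above the duration therefore keeps all points rather than
  erroring.
* Column means use a single NA-padded `colMeans()` rectangle, covering
  integer and fractional $K$ alike; its agreement with a naive double loop
  to a relative 1e-12 is part of the test suite.
* A constant series is a hard error for every method (the variance ratio is
  0/0), not a zero statistic.

## Scale of the shipped checks

The test suite and the benchmark script are sized for a single CPU: the
mean-absolute-error benchmark uses the full 100 replicates per condition
(matching the headline tables it reproduces, about 15 s), null-calibration
and uniformity checks use 1000 noise replicates at N ≤ 300, and pinning
contrasts use 100 replicates across four true periods. Larger replication
(e.g. 1000 per cell) tightens the Monte-Carlo error on mean absolute
errors from roughly ±0.05 h to ±0.015 h and is a one-line change to the
sweep call, but is not run by default.

## Known limitations

* Even sampling only; the Lomb-Scargle method could in principle accept
  uneven data, but the package's scope is the even-sampling comparison.
* No significance machinery for the spectral methods (false-alarm
  probabilities), and no multiple-testing correction across test periods —
  estimation uses the argmax only.
* The CSP p-values rely on the chi-square approximation; for series much
  shorter than ~5 cycles the approximation is known to be rough, which is
  one more reason the package compares methods via estimates rather than
  via p-value magnitudes.
* Period changes over time (e.g. after an environmental manipulation) are
  out of scope; all methods assume a single stationary period.
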
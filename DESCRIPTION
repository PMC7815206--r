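Package: rhythmogram
Title: Period Estimation for Biological Rhythms with Chi-Square, Lomb-Scargle and FFT Periodograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the period of circadian and other biological
    rhythms from evenly sampled time-courses. Implements three variants of the
    chi-square periodogram (the standard Sokolove-Bushell form, a conservative
    form that holds the row count fixed, and a greedy form that uses every
    time-point), together with Lomb-Scargle and zero-padded FFT baselines.
    Includes a simulator of rhythmic time-courses (sinusoid, smooth sawtooth,
    smooth square; Gaussian or Poisson noise), analytic localization of the
    periodogram discontinuities that bias the standard chi-square method, and a
    Monte-Carlo sweep runner that quantifies period-estimation error across
    time-course lengths, true periods, amplitudes and waveforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
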
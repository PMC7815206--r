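test_that("grid layouts satisfy the variant-specific K, D and column counts", {
  l <- csp_layout(680, 226, "standard")
  expect_equal(l$K, 3)
  expect_equal(l$D, 2L)
  expect_equal(l$included, 678L)

  l <- csp_layout(7, 2, "greedy")
  expect_equal(l$K, 3.5)
  expect_equal(l$D, 0L)
  expect_equal(l$column_counts, c(4L, 3L))

  l <- csp_layout(300, 200, "conservative", pmax_samples = 300)
  expect_equal(l$K, 1)
  expect_equal(l$D, 100L)
  expect_equal(l$included, 200L)

  for (v in c("standard", "conservative", "greedy")) {
    l <- csp_layout(8, 8, v, pmax_samples = 8)
    expect_equal(l$K, 1)
    expect_equal(l$D, 0L)
    expect_equal(l$included, 8L)
  }

  expect_error(csp_layout(100, 150, "standard"), "p_samples")
  expect_error(csp_layout(300, 200, "conservative", pmax_samples = 400),
               "shorter than test period range")
})

test_that("Q_P matches hand evaluation and the P = N identity", {
  tc <- timecourse(c(1, 3, 1, 3, 1, 3, 1, 3), 1)
  st <- qp_statistic(tc, csp_layout(8, 2, "standard"))
  expect_equal(st$Qp, 8)
  expect_equal(st$df, 1L)

  # K = 1, D = 0: column means are the data, so Q_P = N for any values
  set.seed(4)
  for (n in c(5, 17, 64)) {
    tc <- timecourse(rnorm(n), 1)
    for (v in c("standard", "greedy")) {
      expect_equal(qp_statistic(tc, csp_layout(n, n, v))$Qp, n)
    }
  }

  expect_error(qp_statistic(timecourse(rep(2, 10), 1), csp_layout(10, 5, "standard")),
               "degenerate")
})

test_that("vectorized Q_P agrees with the naive double-loop oracle", {
  tc7 <- timecourse(c(1, 3, 1, 3, 1, 3, 1), 1)
  expect_equal(qp_statistic(tc7, csp_layout(7, 2, "greedy"))$Qp,
               qp_loop_oracle(tc7$value, 2, "greedy"),
               tolerance = 1e-12)

  set.seed(7)
  for (rep_i in 1:8) {
    n <- sample(20:200, 1)
    x <- rnorm(n) + sin(2 * pi * seq_len(n) / 13)
    tc <- timecourse(x, 1)
    pmax <- n %/% 2
    for (p in sort(sample(3:pmax, 4))) {
      for (v in c("standard", "conservative", "greedy")) {
        got <- qp_statistic(tc, csp_layout(n, p, v, pmax_samples = pmax))$Qp
        want <- qp_loop_oracle(x, p, v, pmax = pmax)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("chi-square p-values are computed in log space without underflow", {
  expect_equal(qp_pvalue_neglog10(0, 1), 0)
  expect_equal(qp_pvalue_neglog10(0, 239), 0)
  # critical value oracle: qchisq is the inverse of the tail probability
  expect_equal(qp_pvalue_neglog10(stats::qchisq(0.95, 1), 1), -log10(0.05),
               tolerance = 1e-9)
  expect_equal(qp_pvalue_neglog10(3.841, 1), 1.301, tolerance = 1e-3)
  big <- qp_pvalue_neglog10(5000, 239)
  expect_true(is.finite(big) && big > 300)  # beyond double's smallest p
  expect_error(qp_pvalue_neglog10(3, 0), "df")
})

test_that("periodograms are well-formed and peak at the true period", {
  tc <- make_sine_tc(period_h = 24, length_h = 72)
  for (v in c("standard", "conservative", "greedy")) {
    pg <- compute_csp(tc, v)
    expect_s3_class(pg, "periodogram")
    expect_equal(nrow(pg), 121)  # P = 180..300 samples
    expect_false(is.unsorted(pg$test_period_h, strictly = TRUE))
    expect_true(all(pg$statistic >= 0))
    expect_true(all(pg$neg_log10_p >= 0))
    expect_equal(pg$df, as.integer(round(pg$test_period_h / 0.1)) - 1L)
  }
  pg_std <- compute_csp(tc, "standard")
  expect_equal(pg_std$test_period_h[which.max(pg_std$neg_log10_p)], 24)

  # greedy D = 0 everywhere; conservative K constant
  expect_true(all(compute_csp(tc, "greedy")$D == 0L))
  pg_con <- compute_csp(tc, "conservative")
  expect_equal(unique(pg_con$K), 2)  # floor(720 / 300)
  # changing pmax changes the conservative K everywhere
  pg_con2 <- compute_csp(tc, "conservative", pmax_h = 24)
  expect_equal(unique(pg_con2$K), 3)  # floor(720 / 240)
})

test_that("greedy equals standard wherever P divides N", {
  tc <- simulate_timecourse(period_h = 24.4, amplitude = 2, length_h = 72,
                            seed = 14)
  pg_s <- compute_csp(tc, "standard")
  pg_g <- compute_csp(tc, "greedy")
  divides <- 720 %% round(pg_s$test_period_h / 0.1) == 0
  expect_equal(sum(divides), 2)  # P = 180 and 240 divide 720
  expect_equal(pg_g$statistic[divides], pg_s$statistic[divides],
               tolerance = 1e-9)
})

test_that("K change points are located analytically", {
  expect_equal(find_k_discontinuities(680, 180, 300),
               tibble::tibble(p_before_samples = 226L, K_before = 3L, K_after = 2L))

  d760 <- find_k_discontinuities(760, 180, 300)
  expect_equal(d760$p_before_samples, c(190L, 253L))
  expect_equal(d760$K_before, c(4L, 3L))
  expect_equal(d760$K_after, c(3L, 2L))

  # exhaustive-scan oracle for N = 720: floor(720/180) = 4 at the grid edge,
  # so the scan sees drops 4 -> 3 (after P = 180) and 3 -> 2 (after P = 240)
  K <- 720 %/% (180:300)
  expect_equal(find_k_discontinuities(720, 180, 300)$p_before_samples,
               (180:300)[which(diff(K) < 0)])

  # the deepest-K transition is reported as the largest discontinuity
  expect_equal(largest_k_discontinuity(720, 180, 300)$period_h, 24)
  expect_equal(largest_k_discontinuity(760, 180, 300)$period_h, 25.3)
})

test_that("null-distribution calibration: mean Q_P and p-value uniformity", {
  n_rep <- 1000

  # E[Q_P] = N_inc (P-1) / (N_inc - 1) under i.i.d. Gaussian noise
  n <- 200; p <- 20
  layout <- csp_layout(n, p, "standard")
  qs <- withr::with_seed(61, replicate(n_rep, {
    qp_statistic(timecourse(rnorm(n), 1), layout)$Qp
  }))
  expected <- n * (p - 1) / (n - 1)
  expect_lt(abs(mean(qs) - expected), 3 * sd(qs) / sqrt(n_rep))

  # with K >= 10 rows the chi-square approximation yields uniform p-values
  n2 <- 300; p2 <- 25
  layout2 <- csp_layout(n2, p2, "standard")
  pvals <- withr::with_seed(62, replicate(n_rep, {
    st <- qp_statistic(timecourse(rnorm(n2), 1), layout2)
    pchisq(st$Qp, st$df, lower.tail = FALSE)
  }))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.001)
})

test_that("greedy periodogram jumps less than standard at every K change", {
  tc <- make_sine_tc(period_h = 24, length_h = 68)  # 680 points
  pg_s <- compute_csp(tc, "standard")
  pg_g <- compute_csp(tc, "greedy")
  disc <- find_k_discontinuities(680, 180, 300)
  p_samples <- round(pg_s$test_period_h / 0.1)
  for (pb in disc$p_before_samples) {
    i <- which(p_samples == pb)
    jump_s <- abs(pg_s$statistic[i + 1] - pg_s$statistic[i])
    jump_g <- abs(pg_g$statistic[i + 1] - pg_g$statistic[i])
    expect_lt(jump_g, jump_s)
  }
})

test_that("periodogram CSV round-trips through the documented schema", {
  tc <- make_sine_tc(length_h = 48)
  for (pg in list(compute_csp(tc, "standard"),
                  lomb_scargle_periodogram(tc))) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_periodogram_csv(pg, path)
    header <- readLines(path, n = 1)
    expect_equal(header, "test_period_h,statistic,df,neg_log10_p,K,D,method")
    back <- read_periodogram_csv(path)
    expect_equal(tidy(back), tidy(pg), tolerance = 1e-12)
  }
})
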
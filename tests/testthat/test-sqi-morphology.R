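test_that("msq matching follows its agreement definition", {
  a <- seq(100, 1000, by = 100)
  expect_equal(sqikit:::msq_from_peaks(a, a, 100, 0.15), 1)
  expect_equal(sqikit:::msq_from_peaks(a, a[1:5], 100, 0.15), 0.5)
  expect_equal(sqikit:::msq_from_peaks(a, a + 5000, 100, 0.15), 0)
  expect_equal(sqikit:::msq_from_peaks(a[1:5], a, 100, 0.15),
               sqikit:::msq_from_peaks(a, a[1:5], 100, 0.15))
  expect_true(is.na(sqikit:::msq_from_peaks(integer(), integer(), 100, 0.15)))
})

test_that("msq on segments is symmetric in detector order and high on clean PPG", {
  out <- clean_ppg(duration_s = 30, hr = 70, seed = 1, noise_sd = 0.01)
  seg <- segment_by_duration(out$record, 30)[[1]]
  m56 <- msq_sqi(seg, 5, 6)
  m65 <- msq_sqi(seg, 6, 5)
  expect_equal(m56, m65)
  expect_gte(m56, 0.9)
  expect_error(msq_sqi(seg, 5, 5), class = "sqikit_config_error")
})

test_that("shift-consistency msq is high on clean PPG", {
  out <- clean_ppg(duration_s = 30, hr = 70, seed = 2, noise_sd = 0.01)
  seg <- segment_by_duration(out$record, 30)[[1]]
  expect_gte(msq_shift_sqi(seg, 5, shift_s = 1), 0.9)
})

test_that("correlogram finds the beat period and sine harmonics", {
  out <- clean_ppg(duration_s = 30, hr = 60, seed = 3, noise_sd = 0.01,
                   hrv_sd_ms = 5)
  cg <- correlogram_sqi(out$record)
  expect_equal(cg$lags_s[1], 1.0, tolerance = 0.05)
  t <- (0:2999) / 100
  cs <- correlogram_sqi(sin(2 * pi * 2 * t), rate = 100, max_lag_s = 2,
                        n_peaks = 3)
  expect_equal(cs$lags_s, c(0.5, 1.0, 1.5), tolerance = 0.011)
  set.seed(4)
  cn <- correlogram_sqi(rnorm(3000), rate = 100)
  expect_true(all(is.na(cn$prominences) | cn$prominences < 0.2))
  cz <- correlogram_sqi(rep(1, 3000), rate = 100)
  expect_true(all(is.na(cz$lags_s)))
})

test_that("correlogram first-peak lag tracks 60/HR across heart rates", {
  for (hr in c(50, 80, 120)) {
    out <- clean_ppg(duration_s = 30, hr = hr, seed = 5, hrv_sd_ms = 5,
                     noise_sd = 0.01)
    cg <- correlogram_sqi(out$record)
    expect_equal(cg$lags_s[1], 60 / hr, tolerance = 0.05 * 60 / hr)
  }
})

test_that("templates are built to their parameterization", {
  tpl <- make_template("ppg_double_gaussian", 100)
  expect_equal(max(abs(tpl$samples)), 1)
  expect_lte(abs(which.max(tpl$samples) / 100 - tpl$params$mu1), 0.02)
  ecg <- make_template("ecg_pqrst_gaussian_sum", 200)
  expect_lte(abs(which.max(ecg$samples) / 200 - 0.40), 0.02)
  expect_lt(min(ecg$samples), 0)  # Q/S deflections
  t1 <- make_template("ppg_double_gaussian", 100)
  t2 <- make_template("ppg_double_gaussian", 200)
  t2r <- stats::approx(seq_along(t2$samples), t2$samples, n = 100)$y
  expect_gt(stats::cor(t1$samples, t2r), 0.999)
  expect_error(make_template("ppg_double_gaussian", 8),
               class = "sqikit_config_error")
  expect_error(make_template("ppg_double_gaussian", 100,
                             params = list(sigma1 = -1)),
               class = "sqikit_config_error")
})

test_that("dtw cost is zero on identity, symmetric, and bounded by perturbation", {
  tpl <- make_template("ppg_double_gaussian", 100)
  expect_equal(dtw_sqi(tpl$samples, tpl), 0)
  beat <- tpl$samples + 0.02 * sin(seq(0, 3, length.out = 100))
  expect_equal(dtw_sqi(beat, tpl$samples), dtw_sqi(tpl$samples, beat))
  delta <- 0.05
  p <- tpl$samples
  p[50] <- p[50] + delta
  # identity-path bound, allowing for the zero-mean/unit-max renormalization
  expect_lte(dtw_sqi(p, tpl), 4 * delta / 100)
  expect_gt(dtw_sqi(p, tpl), 0)
  expect_true(is.na(dtw_sqi(rep(1, 50), tpl)))
})

test_that("dtw cost grows with noise amplitude in expectation", {
  tpl <- make_template("ppg_double_gaussian", 100)
  mean_cost <- vapply(c(0.01, 0.05, 0.2), function(sd) {
    mean(vapply(1:50, function(s) {
      set.seed(s)
      dtw_sqi(tpl$samples + rnorm(100, 0, sd), tpl)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cost) > 0))
})

test_that("qrs energy concentrates for in-band tones", {
  t <- (0:7499) / 250
  expect_gte(qrs_energy_sqi(sin(2 * pi * 10 * t), rate = 250), 0.95)
  expect_lte(qrs_energy_sqi(sin(2 * pi * 30 * t), rate = 250), 0.05)
  set.seed(6)
  expect_equal(qrs_energy_sqi(rnorm(30000), rate = 250), 10 / 35,
               tolerance = 0.05)
})

test_that("amplitude ratios follow beat construction", {
  ecg_beat <- c(seq(0, 1, length.out = 50), seq(1, -0.3, length.out = 50))
  ar <- amplitude_ratio_sqi(list(ecg_beat), "ecg")
  expect_equal(ar$mean, 1.3)
  tpl <- make_template("ppg_double_gaussian", 100, params = list(a = 0.5))
  pr <- amplitude_ratio_sqi(list(tpl$samples), "ppg")
  expect_equal(pr$mean, 2.0, tolerance = 0.1)
  single <- make_template("ppg_double_gaussian", 100, params = list(a = 0))
  expect_true(is.na(suppressMessages(
    amplitude_ratio_sqi(list(single$samples), "ppg")$mean)))
  expect_true(is.na(amplitude_ratio_sqi(list(), "ppg")$mean))
})
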
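test_that("every detector finds the unique peak of a single Gaussian pulse", {
  x <- exp(-0.5 * ((0:999 - 500) / 20)^2)
  for (d in 1:7) {
    ann <- detect_peaks(x, d, params = list(rate = 100, signal_type = "ppg"))
    expect_length(ann$peak_indices, 1)
    expect_lte(abs(ann$peak_indices - 501), 1)
  }
})

test_that("every detector returns zero peaks on a constant segment", {
  for (d in 1:7) {
    ann <- detect_peaks(rep(3.2, 1000), d, params = list(rate = 100))
    expect_length(ann$peak_indices, 0)
  }
})

test_that("detectors 4-7 count beats correctly on clean 60 bpm PPG", {
  out <- clean_ppg(duration_s = 60, hr = 60, seed = 1)
  tol <- 0.03 * 100  # +/- 30 ms
  for (d in 4:7) {
    ann <- detect_peaks(out$record, d)
    expect_true(abs(length(ann$peak_indices) - 60) <= 1,
                label = sprintf("detector %d found %d peaks", d,
                                length(ann$peak_indices)))
    rp <- match_peaks(ann$peak_indices, out$truth$peak_indices, tol)
    expect_gte(rp[["recall"]], 0.95)
    expect_gte(rp[["precision"]], 0.95)
  }
})

test_that("default detector keeps recall/precision >= 0.95 across 40-180 bpm", {
  tol <- 0.05 * 100  # +/- 50 ms
  for (hr in c(40, 60, 90, 120, 150, 180)) {
    out <- clean_ppg(duration_s = 60, hr = hr, seed = 2, hrv_sd_ms = 25,
                     noise_sd = 0.02, wander = c(0.1, 0.2))
    ann <- detect_peaks(out$record, 5)
    rp <- match_peaks(ann$peak_indices, out$truth$peak_indices, tol)
    expect_gte(rp[["recall"]], 0.95)
    expect_gte(rp[["precision"]], 0.95)
  }
})

test_that("ECG R-peak detection via the squared-derivative path works", {
  out <- synth_record(synthesis_spec("ecg", duration_s = 60, rate = 250,
                                     heart_rate_bpm = 70, hrv_sd_ms = 20,
                                     noise_sd = 0.02, seed = 6))
  ann <- detect_peaks(out$record, 5)
  rp <- match_peaks(ann$peak_indices, out$truth$peak_indices, tol = 0.05 * 250)
  expect_gte(rp[["recall"]], 0.95)
  expect_gte(rp[["precision"]], 0.95)
})

test_that("detectors are translation-equivariant", {
  out <- clean_ppg(duration_s = 70, hr = 75, seed = 3, noise_sd = 0.01)
  x <- out$record$samples
  k <- 137L
  n <- 6000L
  for (d in 1:7) {
    p0 <- detect_peaks(x[1:n], d, params = list(rate = 100))$peak_indices
    p1 <- detect_peaks(x[(1 + k):(n + k)], d,
                       params = list(rate = 100))$peak_indices + k
    # compare away from the window edges where content differs
    interior <- function(p) p[p > k + 200 & p < n - 200]
    expect_equal(interior(p1), interior(p0))
  }
})

test_that("relative-threshold detectors are amplitude-scale invariant", {
  out <- clean_ppg(duration_s = 30, hr = 80, seed = 4, noise_sd = 0.02)
  x <- out$record$samples
  for (d in c(1, 3, 5, 6, 7)) {
    p1 <- detect_peaks(x, d, params = list(rate = 100))$peak_indices
    p2 <- detect_peaks(7.3 * x, d, params = list(rate = 100))$peak_indices
    expect_identical(p1, p2)
  }
})

test_that("unknown detector and all-invalid segments raise classed errors", {
  expect_error(detect_peaks(rnorm(500), 9, params = list(rate = 100)),
               class = "sqikit_config_error")
  seg <- waveform_segment(1, 0, 500, rep(NaN, 500), sampling_rate = 100)
  expect_error(detect_peaks(seg, 5), class = "sqikit_input_error")
})

test_that("troughs are the earliest minimum strictly between peaks", {
  x <- c(0, 5, 1, 0.5, 2, 0.5, 5, 0)
  ann <- peak_annotation(c(2L, 7L), detector_id = 6L)
  tr <- detect_troughs(x, ann)
  expect_equal(tr$trough_indices, 4L)  # first of the tied 0.5 values
  one <- detect_troughs(x, peak_annotation(2L))
  expect_length(one$trough_indices, 0)
})

test_that("troughs on clean PPG fall near generator cycle boundaries", {
  out <- clean_ppg(duration_s = 30, hr = 60, seed = 5)
  ann <- detect_troughs(out$record, detect_peaks(out$record, 5))
  onsets <- out$truth$beat_onsets
  for (t in ann$trough_indices) {
    expect_lte(min(abs(onsets - t)), 0.05 * 100)  # +/- 50 ms
  }
})

test_that("beat extraction resamples, zeroes the baseline, skips bad durations", {
  x <- rep(make_template("ppg_double_gaussian", 100)$samples, 5)
  beats <- extract_beats(x, troughs = c(1L, 101L, 201L), target_len = 80,
                         rate = 100)
  expect_length(beats, 2)
  expect_true(all(vapply(beats, length, 1L) == 80))
  expect_true(all(vapply(beats, function(b) b[1], 1) == 0))
  # a 10-sample (0.1 s) beat is outside [0.25, 2] s and is skipped
  skipped <- extract_beats(x, troughs = c(1L, 11L, 111L), target_len = 80,
                           rate = 100)
  expect_length(skipped, 1)
})

test_that("beats extracted from clean PPG are mutually consistent", {
  out <- clean_ppg(duration_s = 30, hr = 60, seed = 7, noise_sd = 0.002)
  ann <- detect_troughs(out$record, detect_peaks(out$record, 5))
  beats <- extract_beats(out$record, ann, target_len = 100)
  expect_gte(length(beats), 20)
  cors <- utils::combn(length(beats), 2, function(ij) {
    stats::cor(beats[[ij[1]]], beats[[ij[2]]])
  })
  expect_gt(min(cors), 0.95)
})
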
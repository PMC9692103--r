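test_that("bandpass filter attenuates out-of-band and passes in-band tones", {
  rate <- 100
  t <- (0:5999) / rate
  spec <- filter_spec("butterworth", 1, 15, 4)
  slow <- waveform_record(sin(2 * pi * 0.05 * t), rate, "ppg")
  fast <- waveform_record(sin(2 * pi * 5 * t), rate, "ppg")
  y_slow <- bandpass_filter(slow, spec)$samples
  y_fast <- bandpass_filter(fast, spec)$samples
  mid <- 2000:4000  # avoid filter edge transients
  expect_lt(max(abs(y_slow[mid])), 0.1)
  expect_gt(max(abs(y_fast[mid])), 0.9)
})

test_that("zero-phase filtering does not shift peak locations", {
  out <- clean_ppg(duration_s = 30, hr = 60, seed = 2, noise_sd = 0.01)
  filt <- bandpass_filter(out$record)
  ann <- detect_peaks(filt, 5)
  rp <- match_peaks(ann$peak_indices, out$truth$peak_indices, tol = 3)
  expect_gte(rp[["recall"]], 0.95)
})

test_that("invalid filter bands raise configuration errors", {
  rec <- waveform_record(rnorm(1000), 100, "ppg")
  expect_error(filter_spec("butterworth", 60, 50), class = "sqikit_config_error")
  expect_error(bandpass_filter(rec, filter_spec("butterworth", 1, 60)),
               class = "sqikit_config_error")
})

test_that("all three filter families are linear in amplitude", {
  rate <- 100
  set.seed(11)
  x <- sin(2 * pi * 2 * (0:1999) / rate) + 0.2 * rnorm(2000)
  for (m in c("butterworth", "chebyshev1", "ellip")) {
    spec <- filter_spec(m, 0.5, 8, 4)
    y1 <- bandpass_filter(waveform_record(x, rate, "ppg"), spec)$samples
    y3 <- bandpass_filter(waveform_record(3 * x, rate, "ppg"), spec)$samples
    expect_equal(y3, 3 * y1, tolerance = 1e-6)
  }
})

test_that("mark_invalid flags exactly the run a run-length scan finds", {
  rate <- 100
  set.seed(3)
  x <- rnorm(60 * rate)
  flat <- (20 * rate + 1):(30 * rate)  # 10 s constant inside 60 s
  x[flat] <- 3.2
  rec <- waveform_record(x, rate, "ppg")
  marked <- mark_invalid(rec, flatline_min_s = 5, zero_run_min_s = 5)
  expect_true(all(!marked$valid_mask[flat]))
  expect_true(all(marked$valid_mask[-flat]))
})

test_that("mark_invalid leaves clean noise untouched and is idempotent", {
  set.seed(4)
  rec <- waveform_record(rnorm(3000), 100, "ppg")
  m1 <- mark_invalid(rec)
  expect_equal(m1$valid_mask, rec$valid_mask)
  nan_rec <- rec
  nan_rec$samples[500:520] <- NaN
  m2 <- mark_invalid(waveform_record(nan_rec$samples, 100, "ppg"),
                     flatline_min_s = 10, zero_run_min_s = 10)
  expect_true(all(!m2$valid_mask[500:520]))
  expect_identical(mark_invalid(m2)$valid_mask, mark_invalid(mark_invalid(m2))$valid_mask)
})

test_that("segmentation tiles the record and drops the partial tail", {
  rec <- waveform_record(rnorm(300 * 100), 100, "ppg")
  segs <- segment_by_duration(rec, 30)
  expect_length(segs, 10)
  spans <- t(vapply(segs, function(s) c(s$start, s$end), numeric(2)))
  expect_equal(spans[, 1], seq(0, 270, by = 30) * 100)
  expect_equal(spans[, 2], spans[, 1] + 3000)
  rec305 <- waveform_record(rnorm(305 * 100), 100, "ppg")
  expect_length(segment_by_duration(rec305, 30), 10)
  short <- waveform_record(rnorm(100), 100, "ppg")
  expect_length(segment_by_duration(short, 30), 0)
})

test_that("invalid-fraction tolerance controls segment validity", {
  rate <- 100
  x <- rnorm(60 * rate)
  x[1:(6 * rate)] <- 7.7  # 20% of the first 30 s segment
  rec <- mark_invalid(waveform_record(x, rate, "ppg"), 2, 2)
  segs_strict <- segment_by_duration(rec, 30, invalid_tolerance = 0.1)
  expect_false(segs_strict[[1]]$valid)
  expect_true(segs_strict[[2]]$valid)
  segs_loose <- segment_by_duration(rec, 30, invalid_tolerance = 0.25)
  expect_true(segs_loose[[1]]$valid)
})

test_that("resampling preserves duration and round-trips band-limited signals", {
  rate <- 100
  t <- (0:999) / rate
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 5 * t)
  rec <- waveform_record(x, rate, "ppg")
  up <- resample_record(rec, 200)
  expect_length(up$samples, 2000)
  expect_equal(duration_s(up), duration_s(rec))
  back <- resample_record(up, 100)
  mid <- 100:900
  expect_gt(stats::cor(back$samples[mid], x[mid]), 0.999)
  expect_identical(resample_record(rec, 100), rec)
  expect_error(resample_record(rec, -1), class = "sqikit_config_error")
})

test_that("taper_and_smooth attenuates endpoints and spikes as designed", {
  beat <- make_template("ppg_double_gaussian", 120)$samples
  expect_equal(taper_and_smooth(beat, "flat", 1), beat)
  spiky <- beat
  spiky[60] <- spiky[60] + 5
  sm <- taper_and_smooth(spiky, "flat", 5)
  expect_lte(sm[60] - beat[60], 5 / 5 + 0.01)  # spike reduced by >= 4/5
  tap <- taper_and_smooth(beat, "tukey", 1)
  expect_lte(abs(tap[1]), 0.01 * max(abs(beat)))
  expect_lte(abs(tap[length(tap)]), 0.01 * max(abs(beat)))
  expect_length(tap, length(beat))
  expect_error(taper_and_smooth(beat, "flat", 120), class = "sqikit_input_error")
})
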
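# Preprocessing: bandpass filtering, invalid-signal marking, segmentation,
# resampling, and per-beat taper/smooth enhancement.

#' Bandpass filter specification
#'
#' @param method `"butterworth"` (default), `"chebyshev1"` or `"ellip"`.
#' @param low_cut,high_cut band edges in Hz; `0 <= low_cut < high_cut` and
#'   `high_cut` must stay below the Nyquist frequency of the record it is
#'   applied to. `low_cut = 0` gives a low-pass filter.
#' @param order filter order (applied forward-backward, so the effective
#'   attenuation is doubled).
#' @param ripple_db passband ripple for chebyshev1/ellip designs (dB).
#' @param stop_atten_db stopband attenuation for the ellip design (dB).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(method = c("butterworth", "chebyshev1", "ellip"),
                        low_cut = 0.5, high_cut = 8, order = 4,
                        ripple_db = 0.5, stop_atten_db = 30) {
  method <- match.arg(method)
  if (!is.finite(low_cut) || !is.finite(high_cut) || low_cut < 0 ||
      low_cut >= high_cut) {
    stop_config("filter band must satisfy 0 <= low_cut < high_cut (got %g, %g)",
                low_cut, high_cut)
  }
  if (order < 1) stop_config("filter order must be >= 1")
  structure(list(method = method, low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), ripple_db = ripple_db,
                 stop_atten_db = stop_atten_db),
            class = "filter_spec")
}

# linear interpolation across invalid samples so the IIR filter never sees
# NaN; the validity mask still marks them afterwards
fill_invalid <- function(x, mask) {
  if (all(mask)) return(x)
  if (!any(mask)) return(rep(0, length(x)))
  idx <- seq_along(x)
  stats::approx(idx[mask], x[mask], xout = idx, rule = 2)$y
}

#' Zero-phase bandpass filter
#'
#' Designs the requested IIR filter and applies it forward-backward
#' (`signal::filtfilt`), so peak locations are not phase-shifted. Invalid
#' samples are bridged by linear interpolation for the filter pass and remain
#' flagged invalid in the output. Output length equals input length.
#'
#' @param record a [waveform_record()].
#' @param spec a [filter_spec()]; default band 0.5-8 Hz (PPG pulse band) for
#'   PPG records and 0.5-40 Hz for ECG.
#' @return filtered [waveform_record()].
#' @examples
#' rec <- waveform_record(sin(2 * pi * 5 * (0:999) / 100), 100, "ppg")
#' filt <- bandpass_filter(rec)
#' @export
bandpass_filter <- function(record, spec = NULL) {
  if (is.null(spec)) {
    spec <- if (record$signal_type == "ecg") {
      filter_spec("butterworth", 0.5, 40, 4)
    } else {
      filter_spec("butterworth", 0.5, 8, 4)
    }
  }
  nyq <- record$sampling_rate / 2
  if (spec$high_cut >= nyq) {
    stop_config("high_cut (%g Hz) must be below Nyquist (%g Hz)",
                spec$high_cut, nyq)
  }
  w <- c(spec$low_cut, spec$high_cut) / nyq
  filt <- if (spec$low_cut <= 0) {
    switch(spec$method,
      butterworth = signal::butter(spec$order, w[2L], type = "low"),
      chebyshev1 = signal::cheby1(spec$order, spec$ripple_db, w[2L], type = "low"),
      ellip = signal::ellip(spec$order, spec$ripple_db, spec$stop_atten_db,
                            w[2L], type = "low"))
  } else {
    switch(spec$method,
      butterworth = signal::butter(spec$order, w, type = "pass"),
      chebyshev1 = signal::cheby1(spec$order, spec$ripple_db, w, type = "pass"),
      ellip = signal::ellip(spec$order, spec$ripple_db, spec$stop_atten_db,
                            w, type = "pass"))
  }
  x <- fill_invalid(record$samples, record$valid_mask)
  y <- signal::filtfilt(filt, x)
  out <- record
  out$samples <- as.numeric(y)
  out$valid_mask <- record$valid_mask & is.finite(out$samples)
  out
}

#' Mark flatline and zero-run samples invalid
#'
#' Quality-control pass over the raw signal: maximal runs of an exactly
#' repeated value lasting at least `flatline_min_s`, and runs of zeros
#' lasting at least `zero_run_min_s`, are flagged invalid (sensor saturation,
#' disconnection, and transmission dropout all present this way). Non-finite
#' samples are always invalid. Samples already invalid stay invalid; the
#' operation is idempotent.
#'
#' @param record a [waveform_record()].
#' @param flatline_min_s minimum constant-run duration to flag, seconds
#'   (default 2; must exceed plausible diastolic plateaus).
#' @param zero_run_min_s minimum zero-run duration to flag, seconds.
#' @return record with an updated validity mask.
#' @export
mark_invalid <- function(record, flatline_min_s = 2, zero_run_min_s = 2) {
  if (flatline_min_s <= 0 || zero_run_min_s <= 0) {
    stop_config("invalid-marking durations must be > 0")
  }
  x <- record$samples
  mask <- record$valid_mask & is.finite(x)
  r <- rle(ifelse(is.finite(x), x, NaN))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flat_n <- ceiling(flatline_min_s * record$sampling_rate)
  zero_n <- ceiling(zero_run_min_s * record$sampling_rate)
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    v <- r$values[i]
    bad <- (len >= flat_n) || (is.finite(v) && v == 0 && len >= zero_n)
    if (bad) mask[starts[i]:ends[i]] <- FALSE
  }
  out <- record
  out$valid_mask <- mask
  out
}

#' Split a record into fixed-duration segments
#'
#' Consecutive non-overlapping segments of exactly `length_s` seconds
#' (half-open 0-based sample spans); the trailing partial segment is dropped.
#' A segment whose invalid-sample fraction exceeds `invalid_tolerance` is
#' flagged `valid = FALSE` and yields an all-NA SQI row downstream.
#'
#' @param record a [waveform_record()] (typically already filtered).
#' @param length_s segment duration, seconds (default 30, long enough for
#'   HRV statistics while limiting artifact exposure).
#' @param invalid_tolerance maximum tolerated invalid-sample fraction
#'   (default 0: any invalid sample invalidates the segment).
#' @param raw_record optional unfiltered record aligned with `record`; its
#'   samples are carried on each segment for SQIs that need the raw signal
#'   (perfusion).
#' @return list of [waveform_segment()]; empty list when the record is
#'   shorter than one segment.
#' @export
segment_by_duration <- function(record, length_s = 30, invalid_tolerance = 0,
                                raw_record = NULL) {
  if (length_s <= 0) stop_config("segment length must be > 0")
  n_per <- as.integer(round(length_s * record$sampling_rate))
  n_seg <- length(record$samples) %/% n_per
  if (n_seg == 0L) return(list())
  raw <- if (is.null(raw_record)) record$samples else raw_record$samples
  lapply(seq_len(n_seg), function(i) {
    start <- (i - 1L) * n_per
    idx <- (start + 1L):(start + n_per)
    frac_invalid <- mean(!record$valid_mask[idx])
    waveform_segment(index = i, start = start, end = start + n_per,
                     filtered_samples = record$samples[idx],
                     raw_samples = raw[idx],
                     sampling_rate = record$sampling_rate,
                     signal_type = record$signal_type,
                     valid = frac_invalid <= invalid_tolerance)
  })
}

#' Resample a record to a new rate
#'
#' Band-limited Fourier resampling: the spectrum is truncated or zero-padded
#' to the new length, which is delay-free and exact for band-limited
#' content. Duration is preserved within one sample period; identity when
#' the target equals the source rate.
#'
#' @param record a [waveform_record()].
#' @param target_rate new sampling rate in Hz.
#' @return resampled [waveform_record()].
#' @export
resample_record <- function(record, target_rate) {
  if (!is.finite(target_rate) || target_rate <= 0) {
    stop_config("target_rate must be > 0, got %g", target_rate)
  }
  if (target_rate == record$sampling_rate) return(record)
  x <- fill_invalid(record$samples, record$valid_mask)
  n_target <- as.integer(round(length(x) * target_rate / record$sampling_rate))
  y <- fft_resample(x, n_target)
  old_t <- (which(!record$valid_mask) - 1L) / record$sampling_rate
  mask <- rep(TRUE, length(y))
  if (length(old_t)) {
    bad <- unique(pmin(length(y), 1L + floor(old_t * target_rate)))
    mask[bad] <- FALSE
  }
  waveform_record(y, target_rate, record$signal_type, record$channel_label,
                  record$start_time, mask)
}

# Fourier-domain resampling to m samples: keep the lowest frequencies,
# splitting (upsample) or folding (downsample) the Nyquist bin
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  k <- min(n, m)               # length whose band limit applies
  nh <- ceiling(k / 2)         # DC + positive-frequency bins kept
  nt <- floor((k - 1) / 2)     # negative-frequency bins kept
  Y[seq_len(nh)] <- X[seq_len(nh)]
  if (nt > 0) Y[(m - nt + 1L):m] <- X[(n - nt + 1L):n]
  if (k %% 2L == 0L) {
    if (m < n) {
      Y[m / 2 + 1L] <- X[m / 2 + 1L] + X[n - m / 2 + 1L]
    } else {
      Y[n / 2 + 1L] <- X[n / 2 + 1L] / 2
      Y[m - n / 2 + 1L] <- X[n / 2 + 1L] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Taper and smooth a single beat
#'
#' Beat enhancement before per-beat SQI computation: a window taper pulls the
#' endpoints toward zero (unifying the beat baseline) and a moving average of
#' width `smooth_len` suppresses isolated spikes. Output length equals input
#' length; `window = "flat"` with `smooth_len = 1` is the identity.
#'
#' @param beat_samples numeric vector, one beat.
#' @param window `"tukey"` (default, flat middle with cosine ends),
#'   `"hann"`, or `"flat"` (no taper).
#' @param smooth_len moving-average width in samples (>= 1, < beat length).
#' @param tukey_alpha fraction of the beat tapered (cosine lobes), default 0.4.
#' @return enhanced beat, same length.
#' @export
taper_and_smooth <- function(beat_samples, window = c("tukey", "hann", "flat"),
                             smooth_len = 1, tukey_alpha = 0.4) {
  window <- match.arg(window)
  n <- length(beat_samples)
  if (smooth_len < 1 || smooth_len >= n) {
    stop_input("smooth_len must satisfy 1 <= smooth_len < beat length")
  }
  w <- switch(window,
    flat = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)),
    tukey = tukey_window(n, tukey_alpha))
  y <- beat_samples * w
  moving_average(y, smooth_len)
}

tukey_window <- function(n, alpha = 0.4) {
  t <- (seq_len(n) - 1L) / (n - 1L)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}
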
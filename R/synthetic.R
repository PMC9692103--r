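# Seeded synthetic ECG/PPG generator with ground-truth beat locations and
# controlled artifact injection. Stands in for device recordings in tests
# and examples; it emulates quasi-periodic beat morphology, beat-to-beat
# interval jitter, additive white noise and baseline wander, but not
# physiological waveform variability (pulse shape is the fixed template).

#' Synthesis specification
#'
#' @param signal_type `"ppg"` or `"ecg"`.
#' @param duration_s recording length in seconds.
#' @param rate sampling rate in Hz (>= 50).
#' @param heart_rate_bpm mean heart rate, 30-220 bpm.
#' @param hrv_sd_ms beat-to-beat interval jitter (Gaussian sd, ms; intervals
#'   truncated at +/- 40% of the mean). Default 25 ms, a realistic resting
#'   sinus variability.
#' @param noise_sd additive white-noise amplitude sd (beat amplitude is 1).
#' @param baseline_wander length-2 numeric `(amplitude, frequency Hz)`;
#'   default a 0.1-amplitude, 0.2 Hz respiratory-scale drift.
#' @param seed integer RNG seed; the same spec always renders bit-identical
#'   output.
#' @return a `synthesis_spec` list.
#' @export
synthesis_spec <- function(signal_type = c("ppg", "ecg"), duration_s = 60,
                           rate = 100, heart_rate_bpm = 75, hrv_sd_ms = 25,
                           noise_sd = 0.02, baseline_wander = c(0.1, 0.2),
                           seed = 1L) {
  signal_type <- match.arg(signal_type)
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220) {
    stop_config("heart_rate_bpm must be in [30, 220], got %g", heart_rate_bpm)
  }
  if (duration_s <= 0) stop_config("duration_s must be > 0")
  if (rate < 50) stop_config("rate must be >= 50 Hz")
  if (length(baseline_wander) != 2L || any(baseline_wander < 0)) {
    stop_config("baseline_wander must be (amplitude, frequency) with both >= 0")
  }
  structure(list(signal_type = signal_type, duration_s = duration_s,
                 rate = rate, heart_rate_bpm = heart_rate_bpm,
                 hrv_sd_ms = hrv_sd_ms, noise_sd = noise_sd,
                 baseline_wander = baseline_wander, seed = as.integer(seed)),
            class = "synthesis_spec")
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic waveform with ground truth
#'
#' Draws beat intervals as truncated Gaussians around `60000/heart_rate_bpm`
#' ms, renders each beat from the idealized PPG or ECG template
#' ([make_template()]), and adds white noise and sinusoidal baseline wander.
#' Identical specs (including the seed) give bit-identical records.
#'
#' @param spec a [synthesis_spec()].
#' @return list with `record` (a [waveform_record()]) and `truth` (list with
#'   1-based `beat_onsets`, `peak_indices` sample indices and an
#'   `artifact_spans` list, empty until [inject_artifact()] is used).
#' @examples
#' out <- synth_record(synthesis_spec("ppg", duration_s = 30, seed = 7))
#' length(out$truth$peak_indices)
#' @export
synth_record <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  with_local_seed(spec$seed, {
    n <- as.integer(round(spec$duration_s * spec$rate))
    mean_ms <- 60000 / spec$heart_rate_bpm
    # draw enough intervals to cover the record, truncated at +/-40%
    n_draw <- as.integer(ceiling(spec$duration_s * 1000 / mean_ms * 1.6)) + 4L
    iv <- stats::rnorm(n_draw, mean_ms, spec$hrv_sd_ms)
    iv <- pmin(pmax(iv, 0.6 * mean_ms), 1.4 * mean_ms)
    onsets_ms <- cumsum(c(0, iv))
    onsets_ms <- onsets_ms[onsets_ms < spec$duration_s * 1000]
    onset_samp <- as.integer(round(onsets_ms / 1000 * spec$rate)) + 1L
    x <- numeric(n)
    peak_idx <- integer()
    kind <- if (spec$signal_type == "ppg") "ppg_double_gaussian" else
      "ecg_pqrst_gaussian_sum"
    for (k in seq_along(onset_samp)) {
      lo <- onset_samp[k]
      hi <- if (k < length(onset_samp)) onset_samp[k + 1L] - 1L else n
      if (hi > n) hi <- n
      len <- hi - lo + 1L
      if (len < 16L) next
      tpl <- make_template(kind, len)
      x[lo:hi] <- x[lo:hi] + tpl$samples
      peak_idx <- c(peak_idx, lo + which.max(tpl$samples) - 1L)
    }
    t <- (seq_len(n) - 1L) / spec$rate
    phase <- stats::runif(1L, 0, 2 * pi)
    if (spec$baseline_wander[1L] > 0) {
      x <- x + spec$baseline_wander[1L] *
        sin(2 * pi * spec$baseline_wander[2L] * t + phase)
    }
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)
    rec <- waveform_record(x, spec$rate, spec$signal_type,
                           channel_label = paste0("synth_", spec$signal_type))
    peak_idx <- peak_idx[peak_idx <= n]
    list(record = rec,
         truth = list(beat_onsets = onset_samp, peak_indices = peak_idx,
                      artifact_spans = list()))
  })
}

#' Inject an artifact into a record
#'
#' Overwrites or perturbs a time span of the record with a controlled
#' artifact, extending the ground truth's artifact span list. Kinds:
#' `flatline` holds the value at span start (loose contact), `dropout_zero`
#' zeroes the span (transmission loss), `spike_burst` adds seeded random
#' impulses of the given magnitude, `gaussian_noise` adds white noise of sd
#' `magnitude`.
#'
#' @param record a [waveform_record()].
#' @param truth ground-truth list from [synth_record()] (or `NULL`).
#' @param kind artifact kind (see above).
#' @param span numeric length-2 `(start_s, end_s)`, half-open, within the
#'   record.
#' @param magnitude spike amplitude or noise sd (ignored for
#'   flatline/dropout).
#' @param seed RNG seed for the stochastic kinds.
#' @return list with the modified `record` and updated `truth`.
#' @export
inject_artifact <- function(record, truth, kind = c("flatline", "dropout_zero",
                                                    "spike_burst", "gaussian_noise"),
                            span, magnitude = 1, seed = 1L) {
  kind <- match.arg(kind)
  n <- length(record$samples)
  if (length(span) != 2L || span[1L] < 0 || span[2L] <= span[1L] ||
      span[2L] > n / record$sampling_rate + 1e-9) {
    stop_input("artifact span must be (start_s, end_s) within the record")
  }
  if (is.null(truth)) truth <- list(artifact_spans = list())
  for (s in truth$artifact_spans) {
    if (identical(s$kind, kind) && span[1L] < s$end_s && s$start_s < span[2L]) {
      stop_input("overlapping '%s' artifact spans", kind)
    }
  }
  lo <- as.integer(floor(span[1L] * record$sampling_rate)) + 1L
  hi <- min(n, as.integer(ceiling(span[2L] * record$sampling_rate)))
  idx <- lo:hi
  x <- record$samples
  x[idx] <- switch(kind,
    flatline = x[lo],
    dropout_zero = 0,
    spike_burst = with_local_seed(seed, {
      out <- x[idx]
      k <- max(1L, as.integer(round(length(idx) / record$sampling_rate * 5)))
      at <- sample(seq_along(idx), k)
      out[at] <- out[at] + magnitude * sample(c(-1, 1), k, replace = TRUE)
      out
    }),
    gaussian_noise = if (magnitude > 0) {
      with_local_seed(seed, x[idx] + stats::rnorm(length(idx), 0, magnitude))
    } else x[idx])
  out <- record
  out$samples <- x
  truth$artifact_spans <- c(truth$artifact_spans,
                            list(list(kind = kind, start_s = span[1L],
                                      end_s = span[2L])))
  list(record = out, truth = truth)
}
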
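# Waveform- and agreement-based SQIs: detector agreement (MSQ), correlogram
# periodicity, beat templates, DTW template matching, QRS-band energy and
# amplitude ratios.

#' Matching of systolic peaks (MSQ)
#'
#' Degree of agreement between two distinct peak detectors on the same
#' segment: peaks are matched greedily one-to-one within `tolerance_s`, and
#' `MSQ = matched / max(|A|, |B|)`, in `[0, 1]`. Symmetric in detector order.
#'
#' @param segment a [waveform_segment()] (or record).
#' @param detector_a,detector_b detector ids 1-7, must differ.
#' @param tolerance_s matching tolerance in seconds (default 0.15, below
#'   half the shortest physiological beat).
#' @param params optional shared detector parameter list.
#' @return agreement fraction; `NA` when both detectors find no peaks.
#' @export
msq_sqi <- function(segment, detector_a = 5L, detector_b = 6L,
                    tolerance_s = 0.15, params = list()) {
  if (detector_a == detector_b) {
    stop_config("msq_sqi needs two distinct detectors")
  }
  a <- detect_peaks(segment, detector_a, params)$peak_indices
  b <- detect_peaks(segment, detector_b, params)$peak_indices
  rate <- seg_rate(segment, params$rate)
  msq_from_peaks(a, b, rate, tolerance_s)
}

msq_from_peaks <- function(a, b, rate, tolerance_s) {
  if (!length(a) && !length(b)) return(NA_real_)
  if (!length(a) || !length(b)) return(0)
  tol <- tolerance_s * rate
  used <- rep(FALSE, length(b))
  matched <- 0L
  for (p in a) {
    d <- abs(b - p)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / max(length(a), length(b))
}

#' Shift-consistency MSQ
#'
#' Runs the same detector on the segment and on the segment shifted
#' `shift_s` seconds forward (leading samples dropped), then measures the
#' agreement of the two peak trains on their overlap. Consistent, clean
#' signals give values near 1; noise-driven detections are unstable under
#' the shift.
#'
#' @param segment a [waveform_segment()] (or record).
#' @param detector_id detector to use.
#' @param shift_s forward shift in seconds (default 1).
#' @param tolerance_s matching tolerance in seconds.
#' @param params optional detector parameter list.
#' @return agreement fraction in `[0, 1]`; `NA` when no peaks at all.
#' @export
msq_shift_sqi <- function(segment, detector_id = 5L, shift_s = 1,
                          tolerance_s = 0.15, params = list()) {
  x <- seg_samples(segment)
  rate <- seg_rate(segment, params$rate)
  k <- as.integer(round(shift_s * rate))
  if (k >= length(x) - 2 * rate) stop_input("shift too large for segment")
  params$rate <- rate
  params$signal_type <- if (inherits(segment, c("waveform_segment", "waveform_record")))
    segment$signal_type else (params$signal_type %||% "ppg")
  a <- detect_peaks(x, detector_id, params)$peak_indices
  b <- detect_peaks(x[(k + 1L):length(x)], detector_id, params)$peak_indices + k
  # compare on the overlap only
  a <- a[a > k]
  msq_from_peaks(a, b, rate, tolerance_s)
}

#' Correlogram SQI
#'
#' Normalized autocorrelation of the segment up to `max_lag_s`; reports the
#' first `n_peaks` local maxima by ascending lag, with their prominences. A
#' quasi-periodic signal shows its beat period as the first correlogram peak;
#' broadband noise shows no prominent peak.
#'
#' @param segment segment/record/numeric vector.
#' @param rate Hz (only for numeric input).
#' @param max_lag_s maximum lag, seconds (default 3).
#' @param n_peaks number of peaks to report (default 3).
#' @return list with `lags_s` and `prominences`, each of length `n_peaks`,
#'   NA-padded when fewer peaks exist; `NA` entries throughout for a
#'   zero-variance segment.
#' @export
correlogram_sqi <- function(segment, rate = NULL, max_lag_s = 3, n_peaks = 3L) {
  x <- seg_samples(segment)
  rate <- seg_rate(segment, rate)
  x <- x[is.finite(x)]
  pad <- function(v) c(v, rep(NA_real_, n_peaks))[seq_len(n_peaks)]
  if (length(x) <= max_lag_s * rate) {
    stop_input("segment shorter than the requested maximum lag")
  }
  if (stats::var(x) == 0) {
    return(list(lags_s = pad(numeric()), prominences = pad(numeric())))
  }
  max_lag <- as.integer(round(max_lag_s * rate))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  cand <- local_maxima(ac)
  if (length(cand)) {
    prom <- peak_prominences(ac, cand)
    ord <- order(cand)
    lags <- (cand[ord] - 1L) / rate
    prom <- prom[ord]
  } else {
    lags <- numeric(); prom <- numeric()
  }
  list(lags_s = pad(lags), prominences = pad(prom))
}

#' Idealized beat templates
#'
#' Mathematically described single-beat waveforms used as DTW references and
#' by the synthetic generator. `ppg_double_gaussian` is a systolic Gaussian
#' bump plus a smaller diastolic bump; `ecg_pqrst_gaussian_sum` is a sum of
#' five signed Gaussians for the P, Q, R, S and T waves. Templates are
#' normalized to unit peak amplitude (`max |samples| = 1`).
#'
#' @param kind `"ppg_double_gaussian"` or `"ecg_pqrst_gaussian_sum"`.
#' @param length template length in samples (>= 16).
#' @param params optional overrides: for PPG `mu1, sigma1, mu2, sigma2, a`
#'   (positions/widths as fractions of the beat, diastolic relative
#'   amplitude `a`); for ECG `mu`, `sigma`, `amp` vectors of length 5
#'   (P, Q, R, S, T).
#' @return object of class `beat_template` with fields `samples`, `kind`,
#'   `length`, `params`.
#' @examples
#' tpl <- make_template("ppg_double_gaussian", 100)
#' which.max(tpl$samples)  # systolic peak near 0.3 of the beat
#' @export
make_template <- function(kind = c("ppg_double_gaussian", "ecg_pqrst_gaussian_sum"),
                          length = 100L, params = list()) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 16L) stop_config("template length must be >= 16 samples")
  t <- (seq_len(length) - 1L) / length
  g <- function(mu, sig) exp(-0.5 * ((t - mu) / sig)^2)
  if (kind == "ppg_double_gaussian") {
    p <- utils::modifyList(list(mu1 = 0.3, sigma1 = 0.1, mu2 = 0.65,
                                sigma2 = 0.12, a = 0.5), params)
    check_template_params(c(p$mu1, p$mu2), c(p$sigma1, p$sigma2))
    y <- g(p$mu1, p$sigma1) + p$a * g(p$mu2, p$sigma2)
  } else {
    p <- utils::modifyList(
      list(mu = c(0.15, 0.35, 0.40, 0.45, 0.70),
           sigma = c(0.035, 0.012, 0.018, 0.012, 0.05),
           amp = c(0.15, -0.15, 1.0, -0.25, 0.35)), params)
    check_template_params(p$mu, p$sigma)
    y <- rowSums(vapply(seq_along(p$mu),
                        function(i) p$amp[i] * g(p$mu[i], p$sigma[i]),
                        numeric(length)))
  }
  y <- y / max(abs(y))
  structure(list(samples = y, kind = kind, length = length, params = p),
            class = "beat_template")
}

check_template_params <- function(mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop_config("template sigma values must be > 0")
  }
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu >= 1)) {
    stop_config("template mu values must lie in [0, 1)")
  }
}

#' @export
print.beat_template <- function(x, ...) {
  cat(sprintf("<beat_template> %s, %d samples\n", x$kind, x$length))
  invisible(x)
}

#' Dynamic-time-warping template-match SQI
#'
#' Classic DTW distance between a beat and an idealized template, both
#' normalized to zero mean and unit max-abs first: local cost `|a - b|`,
#' full alignment (no warping-window constraint), accumulated path cost
#' divided by path length. 0 iff the sequences are identical after
#' normalization; symmetric in its arguments.
#'
#' @param beat numeric beat (length >= 4).
#' @param template a `beat_template` or numeric vector.
#' @return mean per-step alignment cost; `NA` for a constant beat.
#' @export
dtw_sqi <- function(beat, template) {
  b <- as.numeric(beat)
  tp <- if (inherits(template, "beat_template")) template$samples else
    as.numeric(template)
  if (length(b) < 4L) stop_input("dtw_sqi: beat must have >= 4 samples")
  nb <- dtw_normalize(b)
  nt <- dtw_normalize(tp)
  if (is.null(nb) || is.null(nt)) {
    sqikit_log("dtw_sqi: degenerate constant sequence, returning NA")
    return(NA_real_)
  }
  dtw_mean_cost(nb, nt)
}

dtw_normalize <- function(x) {
  x <- x - mean(x)
  m <- max(abs(x))
  if (m == 0) return(NULL)
  x / m
}

# accumulated-cost DTW with |a-b| local cost; returns path cost / path length
dtw_mean_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  INF <- .Machine$double.xmax
  # track path length alongside cost so the mean uses the argmin path's length
  D <- matrix(INF, n + 1L, m + 1L)
  S <- matrix(0L, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    ci <- a[i]
    for (j in seq_len(m)) {
      cost <- abs(ci - b[j])
      d1 <- D[i, j]; d2 <- D[i, j + 1L]; d3 <- D[i + 1L, j]
      if (d1 <= d2 && d1 <= d3) {
        D[i + 1L, j + 1L] <- cost + d1; S[i + 1L, j + 1L] <- 1L + S[i, j]
      } else if (d2 <= d3) {
        D[i + 1L, j + 1L] <- cost + d2; S[i + 1L, j + 1L] <- 1L + S[i, j + 1L]
      } else {
        D[i + 1L, j + 1L] <- cost + d3; S[i + 1L, j + 1L] <- 1L + S[i + 1L, j]
      }
    }
  }
  D[n + 1L, m + 1L] / S[n + 1L, m + 1L]
}

#' QRS-band energy SQI
#'
#' Relative spectral power of the QRS complex band: numerator [5, 15) Hz
#' over denominator [5, 40) Hz. A clean QRS concentrates energy in the
#' numerator band; high-frequency noise spreads it upward.
#'
#' @param segment ECG segment/record/numeric vector.
#' @param rate Hz (>= 80 so the 40 Hz band edge is resolvable).
#' @return power fraction in `[0, 1]`; `NA` when denominator power is 0.
#' @export
qrs_energy_sqi <- function(segment, rate = NULL) {
  x <- seg_samples(segment)
  rate <- seg_rate(segment, rate)
  if (rate < 80) stop_config("qrs_energy_sqi needs rate >= 80 Hz")
  relative_power_sqi(x, rate, num_band = c(5, 15), den_band = c(5, 40))
}

#' Per-beat amplitude ratio SQI
#'
#' ECG: per-beat peak-to-nadir amplitude (max - min). PPG: systolic over
#' diastolic amplitude ratio, where the diastolic shoulder is the highest
#' local maximum after the beat's global maximum (`NA`, with a log entry,
#' when no such shoulder exists). Aggregated to mean and sd over the beats.
#'
#' @param beats list of numeric beats (as from [extract_beats()]).
#' @param signal_type `"ppg"` or `"ecg"`.
#' @return list with `mean` and `std`; both `NA` for an empty beat list.
#' @export
amplitude_ratio_sqi <- function(beats, signal_type = c("ppg", "ecg")) {
  signal_type <- match.arg(signal_type)
  if (!length(beats)) return(list(mean = NA_real_, std = NA_real_))
  vals <- vapply(beats, function(b) {
    if (signal_type == "ecg") return(max(b) - min(b))
    i_sys <- which.max(b)
    if (i_sys >= length(b) - 1L) return(NA_real_)
    tail_part <- b[(i_sys + 1L):length(b)]
    lm <- local_maxima(tail_part)
    if (!length(lm)) return(NA_real_)
    dia <- max(tail_part[lm])
    base <- min(b)
    if (dia - base <= 0) return(NA_real_)
    (b[i_sys] - base) / (dia - base)
  }, numeric(1L))
  if (signal_type == "ppg" && anyNA(vals)) {
    sqikit_log("amplitude_ratio_sqi: %d beat(s) without a diastolic shoulder",
               sum(is.na(vals)))
  }
  ok <- vals[is.finite(vals)]
  if (!length(ok)) return(list(mean = NA_real_, std = NA_real_))
  list(mean = mean(ok), std = if (length(ok) > 1L) stats::sd(ok) else 0)
}
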
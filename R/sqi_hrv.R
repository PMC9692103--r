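# NN-interval construction with ectopic-beat removal and the HRV-based SQIs.

#' Build an NN-interval series from detected peaks
#'
#' Converts peak sample indices to beat-to-beat intervals in milliseconds and
#' removes ectopic (false) intervals. The Malik rule drops an interval
#' deviating more than 20% from the last kept interval; the median rule drops
#' intervals deviating more than 30% from a running 5-point median of the
#' series.
#'
#' @param peaks a [peak_annotation()] or integer vector of peak indices.
#' @param rate sampling rate, Hz.
#' @param ectopic_rule `"malik"`, `"median"`, or `"none"`.
#' @return object of class `nn_intervals`: list with `intervals_ms` (kept
#'   intervals), `source_peaks`, `n_removed_ectopic`, and `raw_intervals_ms`.
#' @examples
#' nn_intervals(c(0, 100, 200, 300), rate = 100, ectopic_rule = "none")
#' @export
nn_intervals <- function(peaks, rate, ectopic_rule = c("malik", "median", "none")) {
  ectopic_rule <- match.arg(ectopic_rule)
  p <- if (inherits(peaks, "peak_annotation")) peaks$peak_indices else
    as.integer(peaks)
  if (length(p) < 3L) stop_input("nn_intervals needs at least 3 peaks")
  raw <- diff(p) / rate * 1000
  keep <- switch(ectopic_rule,
                 none = rep(TRUE, length(raw)),
                 malik = malik_keep(raw),
                 median = median_keep(raw))
  structure(list(intervals_ms = raw[keep], source_peaks = p,
                 n_removed_ectopic = sum(!keep), raw_intervals_ms = raw,
                 ectopic_rule = ectopic_rule),
            class = "nn_intervals")
}

# Malik criterion with last-kept reference: interval i is ectopic when it
# deviates from the most recent kept interval by more than 20% of that
# reference. The first interval is always kept.
malik_keep <- function(raw, frac = 0.2) {
  keep <- logical(length(raw))
  ref <- raw[1L]
  keep[1L] <- TRUE
  for (i in seq_along(raw)[-1L]) {
    if (abs(raw[i] - ref) <= frac * ref) {
      keep[i] <- TRUE
      ref <- raw[i]
    }
  }
  keep
}

median_keep <- function(raw, frac = 0.3, width = 5L) {
  k <- min(width, length(raw))
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 1L) k <- 1L
  med <- stats::runmed(raw, k = k, endrule = "median")
  abs(raw - med) <= frac * med
}

#' @export
print.nn_intervals <- function(x, ...) {
  cat(sprintf("<nn_intervals> %d intervals (%d ectopic removed, rule %s), mean %.1f ms\n",
              length(x$intervals_ms), x$n_removed_ectopic, x$ectopic_rule,
              mean(x$intervals_ms)))
  invisible(x)
}

#' Time-domain HRV SQIs
#'
#' Computes the standard time-domain heart-rate-variability statistics from
#' an NN-interval series: `mean_nni` (ms), `sdnn` (sample sd of intervals),
#' `sdsd` (sample sd of successive differences), `rmssd` (root mean square of
#' successive differences), the coefficient-of-variation forms `cvsd`
#' (rmssd/mean_nni) and `cvnni` (sdnn/mean_nni), `pnn_50`/`pnn_20` (fraction
#' of successive differences exceeding 50/20 ms), and the heart-rate series
#' summaries `hr_mean`, `hr_std`, `hr_min`, `hr_max` (bpm, from 60000/nn).
#'
#' The pNN denominators use the number of successive differences (each
#' comparison is per-difference); sample (n-1) standard deviations follow the
#' HRV literature convention.
#'
#' @param nn an `nn_intervals` object or numeric vector of intervals (ms).
#' @return named list of the 12 measures; difference-based measures are `NA`
#'   with fewer than 3 intervals.
#' @export
hrv_time_sqi <- function(nn) {
  v <- if (inherits(nn, "nn_intervals")) nn$intervals_ms else as.numeric(nn)
  out <- list(mean_nni = NA_real_, sdnn = NA_real_, sdsd = NA_real_,
              rmssd = NA_real_, cvsd = NA_real_, cvnni = NA_real_,
              pnn_50 = NA_real_, pnn_20 = NA_real_, hr_mean = NA_real_,
              hr_std = NA_real_, hr_min = NA_real_, hr_max = NA_real_)
  if (length(v) < 2L) return(out)
  out$mean_nni <- mean(v)
  out$sdnn <- stats::sd(v)
  hr <- 60000 / v
  out$hr_mean <- mean(hr)
  out$hr_std <- stats::sd(hr)
  out$hr_min <- min(hr)
  out$hr_max <- max(hr)
  out$cvnni <- out$sdnn / out$mean_nni
  d <- diff(v)
  if (length(d) >= 2L) {
    out$rmssd <- sqrt(mean(d^2))
    out$sdsd <- stats::sd(d)
    out$cvsd <- out$rmssd / out$mean_nni
    out$pnn_50 <- mean(abs(d) > 50)
    out$pnn_20 <- mean(abs(d) > 20)
  } else if (length(d) == 1L) {
    out$rmssd <- abs(d)
    out$cvsd <- out$rmssd / out$mean_nni
    out$pnn_50 <- mean(abs(d) > 50)
    out$pnn_20 <- mean(abs(d) > 20)
  }
  out
}

#' Frequency-domain HRV SQIs
#'
#' Interpolates the NN series to an evenly sampled tachogram (cubic spline,
#' default 4 Hz), estimates the PSD by Welch's method, and integrates the
#' conventional bands: VLF [0.003, 0.04) Hz, LF [0.04, 0.15) Hz and
#' HF [0.15, 0.4) Hz. Powers are in ms^2.
#'
#' @param nn an `nn_intervals` object or numeric interval vector (ms);
#'   must span at least 60 s.
#' @param interp_rate tachogram sampling rate, Hz.
#' @return named list `lf`, `hf`, `lf_hf_ratio`, `total_power`, `vlf`; all
#'   `NA` when the span is too short.
#' @export
hrv_freq_sqi <- function(nn, interp_rate = 4) {
  v <- if (inherits(nn, "nn_intervals")) nn$intervals_ms else as.numeric(nn)
  na_map <- list(lf = NA_real_, hf = NA_real_, lf_hf_ratio = NA_real_,
                 total_power = NA_real_, vlf = NA_real_)
  if (length(v) < 4L) return(na_map)
  t_beats <- cumsum(v) / 1000  # beat times in s
  span <- t_beats[length(t_beats)] - t_beats[1L]
  if (span < 60) return(na_map)
  grid <- seq(t_beats[1L], t_beats[length(t_beats)], by = 1 / interp_rate)
  tach <- stats::spline(t_beats, v, xout = grid, method = "natural")$y
  nper <- min(length(tach), as.integer(round(interp_rate * 120)))
  spec <- welch_psd(tach, interp_rate, nperseg = nper)
  vlf <- band_power(spec, c(0.003, 0.04))
  lf <- band_power(spec, c(0.04, 0.15))
  hf <- band_power(spec, c(0.15, 0.4))
  list(lf = lf, hf = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
       total_power = band_power(spec, c(0.003, interp_rate / 2)),
       vlf = vlf)
}

#' Ectopic-fraction SQI
#'
#' Fraction of raw beat-to-beat intervals flagged as ectopic by the Malik
#' rule, in `[0, 1]`. Noisy segments with spurious peak detections score
#' high; clean regular rhythms score 0.
#'
#' @param nn_raw an `nn_intervals` object (its raw, pre-filtering intervals
#'   are used) or a numeric vector of raw intervals (ms).
#' @return fraction in `[0, 1]`.
#' @export
ectopic_sqi <- function(nn_raw) {
  raw <- if (inherits(nn_raw, "nn_intervals")) nn_raw$raw_intervals_ms else
    as.numeric(nn_raw)
  if (length(raw) < 1L) return(NA_real_)
  mean(!malik_keep(raw))
}
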
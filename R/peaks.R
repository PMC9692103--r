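# Seven heartbeat peak detectors, trough detection, and beat extraction.
#
# All detectors are deterministic, enforce a refractory period between
# reported peaks, and break amplitude ties toward the earliest index. Peak
# indices are 1-based positions within the segment's sample vector.

DETECTOR_NAMES <- c("adaptive_threshold", "count_origin", "clustering",
                    "slope_sum", "moving_average", "local_max_prominence",
                    "billauer")

#' Peak annotation
#'
#' @param peak_indices,trough_indices strictly increasing 1-based sample
#'   indices within the segment.
#' @param detector_id integer 1-7.
#' @param params list of the detector parameters used.
#' @return object of class `peak_annotation`.
#' @export
peak_annotation <- function(peak_indices, trough_indices = integer(),
                            detector_id = NA_integer_, params = list()) {
  peak_indices <- as.integer(peak_indices)
  trough_indices <- as.integer(trough_indices)
  stopifnot(!is.unsorted(peak_indices, strictly = TRUE),
            !is.unsorted(trough_indices, strictly = TRUE))
  structure(list(peak_indices = peak_indices, trough_indices = trough_indices,
                 detector_id = as.integer(detector_id), params = params),
            class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat(sprintf("<peak_annotation> detector %d (%s): %d peaks, %d troughs\n",
              x$detector_id,
              if (!is.na(x$detector_id)) DETECTOR_NAMES[x$detector_id] else "?",
              length(x$peak_indices), length(x$trough_indices)))
  invisible(x)
}

seg_samples <- function(segment) {
  if (inherits(segment, "waveform_segment")) segment$filtered_samples
  else if (inherits(segment, "waveform_record")) segment$samples
  else as.numeric(segment)
}

seg_rate <- function(segment, rate = NULL) {
  if (inherits(segment, c("waveform_segment", "waveform_record"))) {
    segment$sampling_rate
  } else {
    if (is.null(rate)) stop_config("numeric input needs an explicit rate")
    rate
  }
}

# indices of strict local maxima; a flat plateau reports its first sample
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

# greedy refractory pruning: keep higher-amplitude peaks first, earliest
# index on ties, drop any peak within min_dist of an already kept one
enforce_refractory <- function(cand, x, min_dist) {
  if (length(cand) <= 1L) return(cand)
  ord <- order(-x[cand], cand)
  kept <- integer()
  for (i in cand[ord]) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# --- detector 1: adaptive amplitude threshold -------------------------------
# Tracks a decaying running maximum of the median-centred signal; a local
# maximum is a peak when it exceeds thr_frac of the envelope at that point.
detect_adaptive_threshold <- function(x, rate, thr_frac = 0.5,
                                      halflife_s = 1.0) {
  z <- x - stats::median(x)
  if (max(abs(z)) == 0) return(integer())
  decay <- exp(log(0.5) / (rate * halflife_s))
  env <- numeric(length(z))
  m <- 0
  for (i in seq_along(z)) {
    m <- max(z[i], m * decay)
    env[i] <- m
  }
  cand <- local_maxima(z)
  cand[z[cand] >= thr_frac * env[cand] & z[cand] > 0]
}

# --- detector 2: count origin ----------------------------------------------
# Validates candidate local maxima by the length of the monotone ascent run
# into the peak and descent run out of it; short-run noise maxima are
# discarded.
detect_count_origin <- function(x, rate, min_run_s = 0.03) {
  cand <- local_maxima(x)
  if (!length(cand)) return(integer())
  min_run <- max(3L, as.integer(round(min_run_s * rate)))
  ok <- vapply(cand, function(i) {
    up <- 0L
    j <- i
    while (j > 1L && x[j - 1L] <= x[j] && up < min_run) {
      up <- up + 1L; j <- j - 1L
    }
    down <- 0L
    j <- i
    n <- length(x)
    while (j < n && x[j + 1L] <= x[j] && down < min_run) {
      down <- down + 1L; j <- j + 1L
    }
    up >= min_run && down >= min_run
  }, logical(1L))
  cand <- cand[ok]
  if (length(cand) > 1L) {
    # run lengths alone pass the diastolic shoulder too; keep the upper
    # amplitude half (>= midrange of validated candidates)
    amp <- x[cand]
    cand <- cand[amp >= (max(amp) + min(amp)) / 2]
  }
  cand
}

# --- detector 3: amplitude clustering --------------------------------------
# Deterministic 2-means on local-maximum amplitudes, centers initialised at
# the min and max amplitude; maxima in the upper cluster are peaks.
detect_clustering <- function(x, rate) {
  cand <- local_maxima(x)
  if (length(cand) < 2L) return(cand)
  amp <- x[cand]
  lo <- min(amp); hi <- max(amp)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) return(cand)
  c1 <- lo; c2 <- hi
  assign_old <- rep(NA, length(amp))
  for (it in seq_len(100L)) {
    upper <- abs(amp - c2) < abs(amp - c1)  # ties go to the lower cluster
    if (identical(upper, assign_old)) break
    assign_old <- upper
    if (any(!upper)) c1 <- mean(amp[!upper])
    if (any(upper)) c2 <- mean(amp[upper])
  }
  cand[upper]
}

# --- detector 4: slope sum function ----------------------------------------
# Windowed sum of positive slopes (onset-sensitive transform); threshold
# crossings are followed by a local search-forward for the signal maximum.
detect_slope_sum <- function(x, rate, window_s = 0.128, search_s = 0.3,
                             thr_frac = 0.5) {
  n <- length(x)
  dx <- pmax(diff(x), 0)
  w <- max(2L, as.integer(round(window_s * rate)))
  ssf <- as.numeric(stats::filter(c(rep(0, w - 1L), dx), rep(1, w),
                                  sides = 1L))[(w - 1L) + seq_along(dx)]
  ssf <- c(0, ssf)
  top <- stats::quantile(ssf, 0.975, names = FALSE)
  thr <- thr_frac * top
  if (!is.finite(thr) || thr <= 0) return(integer())
  above <- ssf > thr
  onsets <- which(above & !c(FALSE, above[-n]))
  srch <- as.integer(round(search_s * rate))
  peaks <- vapply(onsets, function(o) {
    hi <- min(n, o + srch)
    p <- o + which.max(x[o:hi]) - 1L
    # the crossing can precede the crest; continue while still ascending
    while (p < n && x[p + 1L] > x[p]) p <- p + 1L
    p
  }, integer(1L))
  sort(unique(peaks))
}

# --- detector 5: two moving averages ---------------------------------------
# Squared positive part of the centred signal; a short beat-scale average
# crossing above a long segment-scale average (plus a small offset) defines
# blocks of interest; the block maximum of the original signal is the peak.
detect_moving_average <- function(x, rate, w_peak_s = 0.111, w_beat_s = 0.667,
                                  beta = 0.02, block_frac = 0.25) {
  z <- pmax(x - mean(x), 0)^2
  if (max(z) == 0) return(integer())
  w1 <- max(2L, as.integer(round(w_peak_s * rate)))
  w2 <- max(w1 + 1L, as.integer(round(w_beat_s * rate)))
  ma_p <- moving_average(z, w1)
  ma_b <- moving_average(z, w2)
  thr <- ma_b + beta * mean(z)
  above <- ma_p > thr
  if (!any(above)) return(integer())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= w1)
  peaks <- vapply(keep, function(k) {
    starts[k] + which.max(x[starts[k]:ends[k]]) - 1L
  }, integer(1L))
  if (length(peaks) > 1L) {
    # a pronounced diastolic wave can clear the threshold as its own block
    # at slow heart rates; drop blocks far below the strongest (squared
    # scale, so this stays amplitude-scale invariant)
    peaks <- peaks[z[peaks] >= block_frac * max(z[peaks])]
  }
  peaks
}

# --- detector 6: local maxima with prominence ------------------------------
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    lmin <- x[p]
    i <- p
    while (i > 1L) {
      i <- i - 1L
      if (x[i] > x[p]) break
      lmin <- min(lmin, x[i])
    }
    left_base <- lmin
    rmin <- x[p]
    i <- p
    n <- length(x)
    while (i < n) {
      i <- i + 1L
      if (x[i] > x[p]) break
      rmin <- min(rmin, x[i])
    }
    x[p] - max(left_base, rmin)
  }, numeric(1L))
}

detect_prominence <- function(x, rate, prom_frac = 0.3) {
  cand <- local_maxima(x)
  if (!length(cand)) return(integer())
  rng <- diff(range(x))
  if (rng == 0) return(integer())
  prom <- peak_prominences(x, cand)
  cand[prom >= prom_frac * rng]
}

# --- detector 7: Billauer delta method -------------------------------------
# Alternating max/min tracker: a maximum is emitted once the signal drops by
# delta below the running maximum, then the tracker switches to minima.
detect_billauer <- function(x, rate, delta_frac = 0.25) {
  rng <- diff(range(x))
  delta <- delta_frac * rng
  if (!is.finite(delta) || delta <= 0) return(integer())
  peaks <- integer()
  mx <- -Inf; mn <- Inf
  mxpos <- NA_integer_
  look_for_max <- TRUE
  for (i in seq_along(x)) {
    v <- x[i]
    if (v > mx) { mx <- v; mxpos <- i }
    if (v < mn) mn <- v
    if (look_for_max) {
      if (v < mx - delta) {
        peaks <- c(peaks, mxpos)
        mn <- v
        look_for_max <- FALSE
      }
    } else {
      if (v > mn + delta) {
        mx <- v; mxpos <- i
        look_for_max <- TRUE
      }
    }
  }
  peaks
}

# Pan-Tompkins-style preconditioning for ECG R-peak detection: derivative,
# squaring, moving-window integration at QRS scale.
ecg_transform <- function(x, rate) {
  d <- c(0, diff(x))
  z <- d^2
  moving_average(z, max(3L, as.integer(round(0.15 * rate))))
}

#' Detect heartbeat peaks in a segment
#'
#' Runs one of seven deterministic peak detectors on a segment, returning
#' candidate systolic peaks (PPG) or R-peaks (ECG). For ECG, detection runs
#' on a squared-derivative, moving-window-integrated transform of the signal
#' and each detection is then refined to the local signal maximum within
#' +/- 50 ms. All detectors enforce a refractory period (default 0.3 s, a
#' 200 bpm ceiling) with earliest-index tie-breaking.
#'
#' Detectors: 1 adaptive amplitude threshold (decaying running maximum);
#' 2 count-origin (monotone ascent/descent run validation); 3 deterministic
#' two-cluster split of local-maximum amplitudes; 4 slope-sum function with
#' threshold crossing and local search; 5 two moving averages (beat-scale vs
#' segment-scale) defining blocks of interest; 6 local maxima with prominence
#' and minimum-distance constraints; 7 Billauer alternating max/min delta
#' tracking.
#'
#' @param segment a [waveform_segment()], [waveform_record()] or numeric
#'   vector (then `rate` is required via `params$rate`).
#' @param detector_id integer 1-7; default 5 (two moving averages).
#' @param params optional list overriding detector parameters
#'   (`refractory_s`, plus per-detector settings such as `thr_frac`,
#'   `min_run_s`, `prom_frac`, `delta_frac`, `beta`; `rate` for plain
#'   numeric input; `precondition = FALSE` disables the ECG transform).
#' @return a [peak_annotation()].
#' @examples
#' x <- synth_record(synthesis_spec("ppg", duration_s = 10, seed = 1))
#' ann <- detect_peaks(x$record, detector_id = 5)
#' @export
detect_peaks <- function(segment, detector_id = 5L, params = list()) {
  detector_id <- as.integer(detector_id)
  if (is.na(detector_id) || detector_id < 1L || detector_id > 7L) {
    stop_config("unknown detector_id %s (must be 1..7)", format(detector_id))
  }
  if (inherits(segment, "waveform_segment") && !segment$valid) {
    stop_input("cannot detect peaks on an invalid segment")
  }
  x <- seg_samples(segment)
  rate <- seg_rate(segment, params$rate)
  if (!all(is.finite(x))) {
    if (!any(is.finite(x))) stop_input("segment is entirely invalid")
    x <- fill_invalid(x, is.finite(x))
  }
  if (length(x) < 2 * rate) stop_input("segment shorter than 2 s")
  refractory_s <- params$refractory_s %||% 0.3
  signal_type <- if (inherits(segment, c("waveform_segment", "waveform_record")))
    segment$signal_type else (params$signal_type %||% "ppg")
  precondition <- params$precondition %||% (signal_type == "ecg")
  x_det <- if (isTRUE(precondition)) ecg_transform(x, rate) else x
  cand <- switch(detector_id,
    detect_adaptive_threshold(x_det, rate,
                              thr_frac = params$thr_frac %||% 0.5,
                              halflife_s = params$halflife_s %||% 1.0),
    detect_count_origin(x_det, rate, min_run_s = params$min_run_s %||% 0.03),
    detect_clustering(x_det, rate),
    detect_slope_sum(x_det, rate,
                     window_s = params$window_s %||% 0.128,
                     search_s = params$search_s %||% 0.3,
                     thr_frac = params$thr_frac %||% 0.5),
    detect_moving_average(x_det, rate,
                          w_peak_s = params$w_peak_s %||% 0.111,
                          w_beat_s = params$w_beat_s %||% 0.667,
                          beta = params$beta %||% 0.02),
    detect_prominence(x_det, rate, prom_frac = params$prom_frac %||% 0.3),
    detect_billauer(x_det, rate, delta_frac = params$delta_frac %||% 0.25))
  if (isTRUE(precondition) && length(cand)) {
    # refine from transform space back to the R-peak of the raw signal
    half <- max(1L, as.integer(round(0.05 * rate)))
    cand <- vapply(cand, function(p) {
      lo <- max(1L, p - half); hi <- min(length(x), p + half)
      lo + which.max(x[lo:hi]) - 1L
    }, integer(1L))
    cand <- sort(unique(cand))
  }
  peaks <- enforce_refractory(cand, x, as.integer(round(refractory_s * rate)))
  peak_annotation(peaks, detector_id = detector_id,
                  params = utils::modifyList(list(refractory_s = refractory_s),
                                             params))
}

#' Detect troughs between consecutive peaks
#'
#' Reports one trough per inter-peak interval: the minimum sample strictly
#' between consecutive peaks, earliest index on ties. Fewer than two peaks
#' yields an empty trough list.
#'
#' @param segment segment/record/numeric vector the peaks were detected on.
#' @param peaks a [peak_annotation()].
#' @return the annotation with `trough_indices` filled in.
#' @export
detect_troughs <- function(segment, peaks) {
  x <- seg_samples(segment)
  p <- peaks$peak_indices
  if (length(p) < 2L) {
    peaks$trough_indices <- integer()
    return(peaks)
  }
  troughs <- vapply(seq_len(length(p) - 1L), function(i) {
    lo <- p[i] + 1L; hi <- p[i + 1L] - 1L
    if (hi < lo) return(NA_integer_)
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1L))
  peaks$trough_indices <- troughs[!is.na(troughs)]
  peaks
}

#' Extract beats between consecutive troughs
#'
#' One beat per consecutive trough pair, linearly resampled to `target_len`
#' samples and baseline-shifted so the first sample is 0. Beats shorter than
#' `min_s` or longer than `max_s` in the original sampling are skipped (with
#' a log entry).
#'
#' @param segment segment/record/numeric vector.
#' @param troughs integer trough indices or a [peak_annotation()].
#' @param target_len output beat length in samples (default 100).
#' @param rate sampling rate, needed only for plain numeric input.
#' @param min_s,max_s admissible beat duration bounds in seconds.
#' @return list of numeric beats, each of length `target_len`.
#' @export
extract_beats <- function(segment, troughs, target_len = 100L, rate = NULL,
                          min_s = 0.25, max_s = 2) {
  x <- seg_samples(segment)
  rate <- seg_rate(segment, rate)
  if (inherits(troughs, "peak_annotation")) troughs <- troughs$trough_indices
  troughs <- as.integer(troughs)
  if (length(troughs) < 2L) return(list())
  beats <- list()
  skipped <- 0L
  for (i in seq_len(length(troughs) - 1L)) {
    lo <- troughs[i]; hi <- troughs[i + 1L]
    len_s <- (hi - lo) / rate
    if (len_s < min_s || len_s > max_s) {
      skipped <- skipped + 1L
      next
    }
    seg <- x[lo:(hi - 1L)]
    beat <- stats::approx(seq_along(seg), seg, n = target_len)$y
    beats[[length(beats) + 1L]] <- beat - beat[1L]
  }
  if (skipped > 0L) {
    sqikit_log("extract_beats: skipped %d beat(s) outside [%g, %g] s", skipped,
               min_s, max_s)
  }
  beats
}

`%||%` <- function(a, b) if (is.null(a)) b else a
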
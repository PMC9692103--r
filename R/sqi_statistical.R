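# Statistical signal quality indices, computable per segment or per beat.

#' Perfusion SQI
#'
#' Pulsatile amplitude of the filtered signal relative to the mean raw
#' signal level: `(max(y) - min(y)) / |mean(x)| * 100`, in percent.
#'
#' @param raw raw amplitude vector `x` (sets the DC reference level).
#' @param filtered filtered amplitude vector `y` over the same span.
#' @return percentage; `NA` when `mean(raw)` is 0.
#' @examples
#' perfusion_sqi(rep(2, 100), seq(0.2, 1.2, length.out = 100))  # 50
#' @export
perfusion_sqi <- function(raw, filtered) {
  m <- abs(mean(raw, na.rm = TRUE))
  if (!is.finite(m) || m == 0) {
    sqikit_log("perfusion_sqi: zero mean raw signal, returning NA")
    return(NA_real_)
  }
  (max(filtered, na.rm = TRUE) - min(filtered, na.rm = TRUE)) / m * 100
}

#' Standardized moment SQIs (skewness, kurtosis)
#'
#' Standardized central moment with 1/N normalization and no bias
#' correction: `mean(((x - mean(x)) / sd_pop)^k)` with the population
#' (1/N) standard deviation. Kurtosis is reported raw (a Gaussian gives 3,
#' not 0); no excess subtraction.
#'
#' @param x amplitude vector.
#' @param order `"skewness"` (third moment) or `"kurtosis"` (fourth).
#' @return dimensionless moment; `NA` for constant input.
#' @export
moment_sqi <- function(x, order = c("skewness", "kurtosis")) {
  order <- match.arg(order)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  mu <- mean(x)
  sig <- sqrt(mean((x - mu)^2))
  if (sig == 0) return(NA_real_)
  z <- (x - mu) / sig
  mean(z^(if (order == "skewness") 3 else 4))
}

#' @rdname moment_sqi
#' @export
skewness_sqi <- function(x) moment_sqi(x, "skewness")

#' @rdname moment_sqi
#' @export
kurtosis_sqi <- function(x) moment_sqi(x, "kurtosis")

#' Energy (Shannon) entropy SQI
#'
#' The signal is scaled to unit energy so the squared samples form a
#' probability distribution, then `-sum(p * log(p))` with `p = x^2 / sum(x^2)`
#' and zero terms contributing 0. Result in nats, in `[0, log(N)]`: a unit
#' impulse gives 0, equal-magnitude samples give `log(N)`. The unit-energy
#' normalization makes the index amplitude-scale invariant.
#'
#' @param x amplitude vector.
#' @return entropy in nats; `NA` for an all-zero signal.
#' @export
entropy_sqi <- function(x) {
  x <- x[is.finite(x)]
  e <- sum(x^2)
  if (length(x) < 1L || e == 0) return(NA_real_)
  p <- x^2 / e
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Signal-to-noise ratio SQI
#'
#' Decomposes the signal into a moving-average trend (`signal_part`) of
#' width `smooth_s` seconds and the residual (`noise_part`); the two parts
#' sum back to the input exactly. Returns `var(signal_part)/var(noise_part)`.
#'
#' @param x amplitude vector.
#' @param rate sampling rate, Hz.
#' @param smooth_s moving-average width in seconds (default 0.05;
#'   `smooth_s * rate` must be at least 3 samples).
#' @return variance ratio; `NA` when the residual variance is 0 (infinite
#'   SNR flagged).
#' @export
snr_sqi <- function(x, rate, smooth_s = 0.05) {
  k <- as.integer(round(smooth_s * rate))
  if (k < 3L) stop_input("snr_sqi: smooth_s * rate must be >= 3 samples")
  d <- decompose_signal(x, rate, smooth_s)
  vs <- stats::var(d$signal_part)
  vn <- stats::var(d$noise_part)
  if (!is.finite(vn) || vn == 0) {
    sqikit_log("snr_sqi: zero-variance residual (infinite SNR), returning NA")
    return(NA_real_)
  }
  vs / vn
}

#' Moving-average signal/noise decomposition
#'
#' @param x amplitude vector.
#' @param rate Hz.
#' @param smooth_s smoothing width in seconds.
#' @return list with `signal_part` and `noise_part`; their sum reconstructs
#'   `x` exactly.
#' @export
decompose_signal <- function(x, rate, smooth_s = 0.05) {
  s <- moving_average(x, as.integer(round(smooth_s * rate)))
  list(signal_part = s, noise_part = x - s)
}

#' Relative spectral power SQI
#'
#' Welch-periodogram power in a numerator band divided by power in a wider
#' denominator band; bands are half-open `[lo, hi)`. The defaults (1-2.25 Hz
#' over 0-8 Hz) bracket the PPG pulse fundamental; a clean pulse concentrates
#' its spectrum there, broadband noise does not.
#'
#' @param x amplitude vector.
#' @param rate Hz; `rate/2` must exceed the denominator's upper edge.
#' @param num_band,den_band band edges in Hz.
#' @param nperseg Welch segment length in samples (default 4 s windows).
#' @return power fraction in `[0, 1]` when `num_band` lies inside
#'   `den_band`; `NA` when the denominator power is 0.
#' @export
relative_power_sqi <- function(x, rate, num_band = c(1, 2.25),
                               den_band = c(0, 8),
                               nperseg = min(length(x), round(4 * rate))) {
  if (rate / 2 <= den_band[2L]) {
    stop_config("relative_power_sqi: Nyquist (%g) must exceed the denominator band edge (%g)",
                rate / 2, den_band[2L])
  }
  spec <- welch_psd(x[is.finite(x)], rate, nperseg = nperseg)
  den <- band_power(spec, den_band)
  if (!is.finite(den) || den == 0) return(NA_real_)
  band_power(spec, num_band) / den
}

#' Zero/mean crossing count SQI
#'
#' Number of consecutive sample pairs with strictly opposite sign relative
#' to the reference level (0, or the signal mean). Samples exactly at the
#' reference carry the sign of the previous off-reference sample, so
#' quantized signals that touch the reference are counted deterministically.
#'
#' @param x amplitude vector.
#' @param mode `"zero"` or `"mean"`.
#' @return crossing count (integer >= 0).
#' @export
crossing_sqi <- function(x, mode = c("zero", "mean")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(0L)
  ref <- if (mode == "mean") mean(x) else 0
  s <- sign(x - ref)
  nz <- s != 0
  if (!any(nz)) return(0L)
  # carry the previous non-reference sign across exact-reference samples
  idx <- cumsum(nz)
  first <- which(nz)[1L]
  carried <- s[nz][pmax(idx, 1L)]
  carried[seq_len(first - 1L)] <- s[nz][1L]
  sum(diff(carried) != 0)
}

#' @rdname crossing_sqi
#' @export
zero_crossing_sqi <- function(x) crossing_sqi(x, "zero")

#' @rdname crossing_sqi
#' @export
mean_crossing_sqi <- function(x) crossing_sqi(x, "mean")
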
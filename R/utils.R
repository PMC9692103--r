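# Internal helpers: classed conditions, moving averages, Welch PSD.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sqikit_config_error", "sqikit_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sqikit_input_error", "sqikit_error")))
}

sqikit_log <- function(msg, ...) {
  if (isTRUE(getOption("sqikit.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(msg, ...))
}

#' Centered moving average with replicated-edge padding
#'
#' Output has the same length as the input, so `x - moving_average(x, k)`
#' is an exact additive decomposition of `x`.
#'
#' @param x numeric vector.
#' @param k window width in samples (coerced to an odd integer >= 1 by
#'   rounding up).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2L))[(h + 1L):(h + length(x))]
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: Hann-windowed segments with 50% overlap,
#' per-segment mean removal, one-sided density scaling (units amplitude^2/Hz).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples; shortened to `length(x)` when the
#'   input is shorter than one segment.
#' @param overlap fractional overlap between segments, default 0.5.
#' @return list with `frequencies` (Hz, from 0 to fs/2) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), round(4 * fs)),
                      overlap = 0.5) {
  stopifnot(fs > 0, length(x) >= 2)
  nperseg <- min(as.integer(nperseg), length(x))
  if (nperseg < 2L) stop_input("welch_psd: input too short")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  # periodic Hann window
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / nperseg)
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  scale2 <- rep(2, nfreq)
  scale2[1L] <- 1
  if (nperseg %% 2L == 0L) scale2[nfreq] <- 1
  list(frequencies = (seq_len(nfreq) - 1L) * fs / nperseg,
       psd = psd * scale2)
}

#' Band power from a spectral estimate
#'
#' Sums PSD bins whose frequency lies in the half-open band `[lo, hi)`,
#' multiplied by the bin width (rectangle integration).
#'
#' @param spec list with `frequencies` and `psd` (see [welch_psd()]).
#' @param band numeric length-2, band edges in Hz; the band is `[lo, hi)`.
#' @return scalar power.
#' @keywords internal
band_power <- function(spec, band) {
  f <- spec$frequencies
  df <- if (length(f) > 1L) f[2L] - f[1L] else 1
  sel <- f >= band[1L] & f < band[2L]
  sum(spec$psd[sel]) * df
}

# first index of the maximum (earliest tie-break)
which_max_first <- function(x) which.max(x)

is_na_scalar <- function(x) length(x) == 1L && is.na(x)
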
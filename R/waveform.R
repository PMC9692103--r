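#' Waveform record container
#'
#' The central container for a single-channel physiological waveform: the
#' sampled amplitudes, their sampling rate, the signal modality (ECG or PPG)
#' and a per-sample validity mask. Samples flagged invalid (missing values,
#' flatlines, zero runs) are kept in place so sample indices stay aligned
#' with the recording; downstream steps honour the mask instead of dropping
#' samples.
#'
#' @param samples numeric vector of amplitudes (arbitrary units). Non-finite
#'   samples are automatically flagged invalid.
#' @param sampling_rate sampling rate in Hz, > 0.
#' @param signal_type `"ppg"` or `"ecg"`.
#' @param channel_label optional channel name.
#' @param start_time optional POSIXct start timestamp.
#' @param valid_mask logical vector, one entry per sample; `NULL` means all
#'   finite samples are valid.
#' @return an object of class `waveform_record`.
#' @examples
#' rec <- waveform_record(sin(2 * pi * (0:999) / 100), 100, "ppg")
#' duration_s(rec)
#' @export
waveform_record <- function(samples, sampling_rate, signal_type = c("ppg", "ecg"),
                            channel_label = "signal", start_time = NULL,
                            valid_mask = NULL) {
  signal_type <- match.arg(tolower(signal_type), c("ppg", "ecg"))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop_input("sampling_rate must be a positive number, got %s",
               format(sampling_rate))
  }
  samples <- as.numeric(samples)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(samples))
  if (length(valid_mask) != length(samples)) {
    stop_input("valid_mask length (%d) != sample count (%d)",
               length(valid_mask), length(samples))
  }
  valid_mask <- valid_mask & is.finite(samples)
  structure(
    list(samples = samples,
         sampling_rate = as.numeric(sampling_rate),
         signal_type = signal_type,
         channel_label = as.character(channel_label),
         start_time = start_time,
         valid_mask = as.logical(valid_mask)),
    class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %s, channel '%s': %d samples @ %g Hz (%.1f s), %d invalid\n",
              toupper(x$signal_type), x$channel_label, length(x$samples),
              x$sampling_rate, duration_s(x), sum(!x$valid_mask)))
  invisible(x)
}

#' Record duration in seconds
#' @param record a [waveform_record()].
#' @return duration in seconds.
#' @export
duration_s <- function(record) length(record$samples) / record$sampling_rate

#' Signal-quality session
#'
#' Accumulates the pipeline state for one recording: the record, its
#' segments, the computed SQI table, the ruleset and the decisions. Each
#' pipeline step fills one slot.
#'
#' @param record a [waveform_record()].
#' @return an object of class `sqi_session`.
#' @export
sqi_session <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  structure(list(record = record, segments = NULL, sqi_table = NULL,
                 ruleset = NULL, decisions = NULL),
            class = "sqi_session")
}

#' @export
print.sqi_session <- function(x, ...) {
  cat("<sqi_session>\n  ")
  print(x$record)
  cat(sprintf("  segments: %s | sqi_table: %s | ruleset: %s | decisions: %s\n",
              if (is.null(x$segments)) "-" else length(x$segments),
              if (is.null(x$sqi_table)) "-" else paste(dim(x$sqi_table), collapse = "x"),
              if (is.null(x$ruleset)) "-" else length(x$ruleset$rules),
              if (is.null(x$decisions)) "-" else nrow(x$decisions)))
  invisible(x)
}

#' Waveform segment
#'
#' A half-open sample span `[start, end)` of a parent record, carrying the
#' filtered samples used for SQI computation and a validity flag. Spans use
#' 0-based sample indexing so segment tiling is unambiguous.
#'
#' @param index ordinal segment number (1-based row id in the SQI table).
#' @param start,end half-open 0-based sample span.
#' @param filtered_samples amplitudes for the span (filtered signal).
#' @param raw_samples raw amplitudes for the span (used by the perfusion SQI).
#' @param sampling_rate Hz.
#' @param signal_type `"ppg"` or `"ecg"`.
#' @param valid logical; FALSE when the invalid-sample fraction exceeded the
#'   segmentation tolerance.
#' @return object of class `waveform_segment`.
#' @export
waveform_segment <- function(index, start, end, filtered_samples,
                             raw_samples = filtered_samples,
                             sampling_rate, signal_type = "ppg", valid = TRUE) {
  stopifnot(end > start, length(filtered_samples) == end - start)
  structure(list(index = as.integer(index), start = as.integer(start),
                 end = as.integer(end),
                 filtered_samples = as.numeric(filtered_samples),
                 raw_samples = as.numeric(raw_samples),
                 sampling_rate = sampling_rate,
                 signal_type = signal_type, valid = isTRUE(valid)),
            class = "waveform_segment")
}

#' @export
print.waveform_segment <- function(x, ...) {
  cat(sprintf("<waveform_segment> #%d [%d, %d) @ %g Hz, %s\n", x$index,
              x$start, x$end, x$sampling_rate,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}
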
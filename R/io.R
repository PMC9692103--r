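# Format dispatch and delimited-text I/O for records, SQI tables, decisions.

read_csv_waveform <- function(path, channel = NULL, sampling_rate = NULL,
                              signal_type = "ppg") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) == 0L || nrow(df) == 0L) stop_input("empty CSV: %s", path)
  time_col <- intersect(c("time", "timestamp", "t"), tolower(names(df)))
  time_idx <- if (length(time_col)) match(time_col[1L], tolower(names(df))) else NA
  if (is.null(channel)) {
    candidates <- setdiff(seq_along(df), time_idx)
    if (!length(candidates)) stop_input("CSV has no signal column: %s", path)
    idx <- candidates[1L]
  } else if (is.character(channel)) {
    idx <- match(channel, names(df))
    if (is.na(idx)) stop_input("CSV column '%s' not found (have: %s)",
                               channel, paste(names(df), collapse = ", "))
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > ncol(df)) stop_input("CSV column index %d out of range", idx)
  }
  x <- suppressWarnings(as.numeric(df[[idx]]))
  if (is.null(sampling_rate)) {
    if (is.na(time_idx)) {
      stop_config("CSV input needs sampling_rate or a time/timestamp column")
    }
    tv <- df[[time_idx]]
    tn <- suppressWarnings(as.numeric(tv))
    if (all(is.na(tn))) {
      tp <- as.POSIXct(tv, tz = "UTC")
      tn <- as.numeric(tp)
    }
    dt <- stats::median(diff(tn), na.rm = TRUE)
    if (!is.finite(dt) || dt <= 0) stop_input("cannot infer sampling rate from time column")
    sampling_rate <- 1 / dt
  }
  waveform_record(x, sampling_rate, signal_type,
                  channel_label = names(df)[idx])
}

#' Read a waveform file into a record
#'
#' Single entry point over the supported formats. Missing or unparseable
#' samples are kept in place and flagged invalid, never dropped, so sample
#' indices stay aligned with the recording.
#'
#' @param path input file (for WFDB, the `.hea` header or basename).
#' @param format `"edf"`, `"wfdb"` or `"csv"`.
#' @param signal_type `"ppg"` or `"ecg"`.
#' @param channel channel label/column name or 1-based index; default is the
#'   first (non-time) channel.
#' @param sampling_rate required for CSV files without a time column, in Hz.
#' @return a [waveform_record()].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write.csv(data.frame(ppg = sin(2 * pi * (0:499) / 100)), p, row.names = FALSE)
#' rec <- read_waveform(p, "csv", "ppg", sampling_rate = 100)
#' @export
read_waveform <- function(path, format = c("csv", "edf", "wfdb"),
                          signal_type = c("ppg", "ecg"), channel = NULL,
                          sampling_rate = NULL) {
  if (length(format) != 1L || !format %in% c("csv", "edf", "wfdb")) {
    stop_config("unknown waveform format '%s' (supported: edf, wfdb, csv)",
                paste(format, collapse = "/"))
  }
  signal_type <- match.arg(tolower(signal_type), c("ppg", "ecg"))
  if (format != "wfdb" && !file.exists(path)) stop_input("file not found: %s", path)
  switch(format,
         csv = read_csv_waveform(path, channel, sampling_rate, signal_type),
         edf = read_edf(path, if (is.null(channel)) 1L else channel, signal_type),
         wfdb = read_wfdb(path, if (is.null(channel)) 1L else channel, signal_type))
}

#' Write a record to a waveform file
#'
#' @param record a [waveform_record()].
#' @param path output path (for WFDB: basename without extension).
#' @param format `"csv"`, `"edf"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path, format = c("csv", "edf", "wfdb")) {
  format <- match.arg(format)
  switch(format,
    csv = {
      x <- record$samples
      x[!record$valid_mask] <- NA_real_
      df <- data.frame(time = (seq_along(x) - 1L) / record$sampling_rate,
                       signal = x)
      names(df)[2L] <- record$channel_label
      utils::write.csv(df, path, row.names = FALSE, na = "NaN")
      invisible(path)
    },
    edf = write_edf(record, path),
    wfdb = write_wfdb(record, path))
}

#' Write an SQI table to CSV
#'
#' One row per segment: `segment_id`, `start_s`, `end_s`, then one column per
#' SQI. Undefined values are serialized as the `NA` token, never as 0.
#' Re-reading with [read_sqi_table()] reproduces the values to full double
#' precision.
#'
#' @param table data frame as produced by [extract_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sqi_table <- function(table, path) {
  if (is.null(table) || !is.data.frame(table) || nrow(table) == 0L) {
    stop_input("write_sqi_table: empty SQI table")
  }
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an SQI table written by [write_sqi_table()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_sqi_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write segment decisions to CSV
#'
#' Columns: `segment_id`, `label` (accept/reject), `triggered_rule`.
#'
#' @param decisions data frame from [classify_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE, na = "")
  invisible(path)
}
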
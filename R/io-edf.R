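# Minimal EDF reader/writer (16-bit European Data Format).
#
# Implements the published fixed-layout ASCII header (256 bytes global +
# 256 bytes per signal) and little-endian int16 data records. Sufficient for
# single- and multi-channel continuous recordings; EDF+ annotation channels
# are exposed as ordinary channels and simply not selected.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Read an EDF file
#'
#' @param path file path.
#' @param channel channel label or 1-based index; default 1.
#' @param signal_type `"ppg"` or `"ecg"`.
#' @return a [waveform_record()]; digital values are rescaled to physical
#'   units using the header's calibration fields.
#' @export
read_edf <- function(path, channel = 1L, signal_type = "ppg") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  start_date <- fld(169, 8)
  start_time <- fld(177, 8)
  n_records <- as.integer(fld(237, 8))
  rec_dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1L) stop_input("EDF header: bad signal count in %s", path)
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sfld <- function(offset, len, i) {
    from <- offset * ns + (i - 1L) * len + 1L
    trimws(substr(sig_hdr, from, from + len - 1L))
  }
  labels <- vapply(seq_len(ns), function(i) sfld(0, 16, i), "")
  if (is.character(channel)) {
    idx <- match(channel, labels)
    if (is.na(idx)) stop_input("EDF channel '%s' not found (have: %s)",
                               channel, paste(labels, collapse = ", "))
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > ns) stop_input("EDF channel index %d out of 1..%d", idx, ns)
  }
  pmin <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8, 8, i), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 8, 8, i), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 16, 8, i), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 24, 8, i), ""))
  spr <- as.integer(vapply(seq_len(ns), function(i) sfld(16 + 80 + 8 + 32 + 80, 8, i), ""))
  rec_len <- sum(spr)
  dig <- readBin(con, "integer", n = rec_len * n_records, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dig) < rec_len * n_records) {
    stop_input("EDF data truncated in %s", path)
  }
  offs <- c(0L, cumsum(spr))
  take <- unlist(lapply(seq_len(n_records) - 1L, function(r) {
    r * rec_len + offs[idx] + seq_len(spr[idx])
  }))
  d <- dig[take]
  gain <- (pmax[idx] - pmin[idx]) / (dmax[idx] - dmin[idx])
  phys <- (d - dmin[idx]) * gain + pmin[idx]
  rate <- spr[idx] / rec_dur
  if (!is.finite(rate) || rate <= 0) stop_input("EDF: non-positive sampling rate")
  st <- tryCatch(
    as.POSIXct(paste(start_date, start_time), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  waveform_record(phys, rate, signal_type, channel_label = labels[idx],
                  start_time = st)
}

#' Write a record to an EDF file
#'
#' One channel, 1-second data records. The sampling rate must round to an
#' integer number of samples per second; a trailing partial second is padded
#' by repeating the last sample (EDF stores whole data records).
#'
#' @param record a [waveform_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  x <- record$samples
  x[!is.finite(x)] <- min(x[is.finite(x)], 0)
  spr <- as.integer(round(record$sampling_rate))
  if (abs(spr - record$sampling_rate) > 1e-9 || spr < 1L) {
    stop_config("EDF writer needs an integer sampling rate, got %g",
                record$sampling_rate)
  }
  n_records <- as.integer(ceiling(length(x) / spr))
  if (n_records * spr > length(x)) {
    x <- c(x, rep(x[length(x)], n_records * spr - length(x)))
  }
  pmin <- min(x); pmax <- max(x)
  if (pmax <= pmin) pmax <- pmin + 1
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin))
  st <- if (inherits(record$start_time, "POSIXct")) record$start_time else
    as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad(format(st, "%d.%m.%y"), 8), edf_pad(format(st, "%H.%M.%S"), 8),
    edf_pad(256L + 256L, 8), edf_pad("", 44),
    edf_pad(n_records, 8), edf_num(1, 8), edf_pad(1L, 4),
    # per-signal header block (one signal)
    edf_pad(record$channel_label, 16), edf_pad("", 80),
    edf_pad("uV", 8), edf_num(pmin, 8), edf_num(pmax, 8),
    edf_num(dmin, 8), edf_num(dmax, 8), edf_pad("", 80),
    edf_pad(spr, 8), edf_pad("", 32))
  writeBin(charToRaw(hdr), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}
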
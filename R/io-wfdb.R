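# Minimal WFDB (PhysioNet/MIT) reader and writer.
#
# Reads the text .hea header plus a single .dat file in format 16 (16-bit
# little-endian) or 212 (packed 12-bit pairs). Writes format 16. The format-16
# sentinel -32768 marks a missing sample and becomes an invalid entry in the
# record mask.

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record_name <- sub("/.*$", "", top[1L])
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    units <- sub("^[^/]*/?", "", gain_field)
    gb <- sub("/.*$", "", gain_field)
    baseline <- if (grepl("\\(", gb)) as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gb)) else NA
    gain <- as.numeric(sub("\\(.*$", "", gb))
    if (!is.finite(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    if (!is.finite(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else
      paste0("sig", i)
    list(file = f[1L], fmt = sub("x.*|:.*|\\+.*", "", f[2L]), gain = gain,
         baseline = baseline, units = units, desc = desc)
  })
  list(record = record_name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, n) {
  readBin(path, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
}

read_dat_212 <- function(path, n) {
  raw <- readBin(path, "raw", n = ceiling(n / 2) * 3)
  b <- as.integer(raw)
  npair <- length(b) %/% 3L
  i <- 3L * (seq_len(npair) - 1L)
  s1 <- b[i + 1L] + bitwShiftL(bitwAnd(b[i + 2L], 0x0FL), 8L)
  s2 <- b[i + 3L] + bitwShiftL(bitwAnd(bitwShiftR(b[i + 2L], 4L), 0x0FL), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- as.integer(rbind(s1, s2))
  out[seq_len(n)]
}

#' Read a WFDB (MIT-format) record
#'
#' @param path path to the `.hea` header (or its basename without extension).
#' @param channel channel description or 1-based index; default 1.
#' @param signal_type `"ppg"` or `"ecg"`.
#' @return a [waveform_record()] in physical units
#'   (`(digital - baseline) / gain`); format-16 sentinel values (-32768) are
#'   marked invalid.
#' @export
read_wfdb <- function(path, channel = 1L, signal_type = "ecg") {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop_input("WFDB header not found: %s", hea_path)
  h <- parse_hea(hea_path)
  if (is.character(channel)) {
    idx <- match(channel, vapply(h$signals, `[[`, "", "desc"))
    if (is.na(idx)) stop_input("WFDB channel '%s' not found", channel)
  } else {
    idx <- as.integer(channel)
    if (idx < 1L || idx > h$nsig) stop_input("WFDB channel index %d out of 1..%d",
                                             idx, h$nsig)
  }
  dat_files <- vapply(h$signals, `[[`, "", "file")
  if (length(unique(dat_files)) != 1L) {
    stop_input("multi-file WFDB records are not supported")
  }
  dat_path <- file.path(dirname(hea_path), dat_files[1L])
  if (!file.exists(dat_path)) stop_input("WFDB data file not found: %s", dat_path)
  fmt <- h$signals[[idx]]$fmt
  ntot <- if (is.na(h$nsamp)) NA_integer_ else h$nsamp * h$nsig
  dig <- switch(fmt,
    "16" = {
      if (is.na(ntot)) ntot <- file.size(dat_path) %/% 2L
      read_dat_16(dat_path, ntot)
    },
    "212" = {
      if (is.na(ntot)) ntot <- (file.size(dat_path) %/% 3L) * 2L
      read_dat_212(dat_path, ntot)
    },
    stop_config("unsupported WFDB format '%s' (supported: 16, 212)", fmt))
  d <- dig[seq(idx, length(dig), by = h$nsig)]
  invalid <- if (fmt == "16") d == -32768L else rep(FALSE, length(d))
  s <- h$signals[[idx]]
  phys <- (as.numeric(d) - s$baseline) / s$gain
  phys[invalid] <- NA_real_
  if (!is.finite(h$fs) || h$fs <= 0) stop_input("WFDB: non-positive sampling rate")
  waveform_record(phys, h$fs, signal_type, channel_label = s$desc)
}

#' Write a record as a WFDB format-16 file pair
#'
#' @param record a [waveform_record()].
#' @param path output path without extension; writes `path.hea` and
#'   `path.dat`. Invalid samples are stored as the format-16 missing-sample
#'   sentinel.
#' @param gain ADC gain (digital units per physical unit).
#' @return `path`, invisibly.
#' @export
write_wfdb <- function(record, path, gain = 1000) {
  base <- sub("\\.hea$", "", path)
  x <- record$samples
  dig <- as.integer(round(x * gain))
  dig[!record$valid_mask | !is.finite(x)] <- -32768L
  dig[dig > 32767L & dig != -32768L] <- 32767L
  dig[dig < -32767L & dig != -32768L] <- -32767L
  rec_name <- basename(base)
  hea <- c(sprintf("%s 1 %g %d", rec_name, record$sampling_rate, length(dig)),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s", rec_name, gain,
                   if (length(dig)) dig[1L] else 0L, record$channel_label))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(base)
}
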
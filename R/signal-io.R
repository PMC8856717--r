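#' Read a multichannel recording
#'
#' Reads a recording written by [write_recording()] (or compatible files) in
#' one of three dialects:
#' \describe{
#'   \item{csv}{plain text, one column per channel, header row of site
#'     labels; an optional first comment line `# fs=... start_time=...
#'     strain=...` carries metadata. If absent, `fs` must be supplied.}
#'   \item{edf}{European Data Format (plain EDF, not EDF+), 16-bit; channel
#'     labels are matched to the site vocabulary via `site_map`, unmatched
#'     labels are tagged `OTHER`. Annotations are kept in a sidecar CSV
#'     (see [read_annotation()]), not embedded.}
#'   \item{rds}{native lossless container (bit-exact round trip).}
#' }
#'
#' @param path file path.
#' @param format one of `"csv"`, `"edf"`, `"rds"`; default guesses from the
#'   file extension.
#' @param fs sampling rate in Hz, required for metadata-less CSV.
#' @param site_map optional named character vector mapping file channel
#'   labels to site labels, e.g. `c("EEG S1-4" = "S1_L4")`.
#' @return A [signal_record()] with amplitudes in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf", "rds"),
                           fs = NULL, site_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_recording_csv(path, fs),
         edf = read_recording_edf(path, site_map),
         rds = {
           rec <- readRDS(path)
           if (!inherits(rec, "SignalRecord")) stop("not a SignalRecord rds file")
           rec
         })
}

#' Write a multichannel recording
#'
#' Counterpart of [read_recording()]. EDF output stores each channel as
#' 16-bit integers over a symmetric physical range covering the channel's
#' amplitude extremes (physical dimension uV), so the round trip is exact up
#' to one quantization step `(phys_max - phys_min) / (dig_max - dig_min)`.
#' CSV and RDS round trips are lossless (up to decimal printing for CSV).
#'
#' @param record a [signal_record()].
#' @param path output file path.
#' @param format one of `"csv"`, `"edf"`, `"rds"`; default guesses from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(record, path, format = c("auto", "csv", "edf", "rds")) {
  stopifnot(inherits(record, "SignalRecord"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (ncol(record$data) < 1L)
    stop("cannot write an empty-duration record")
  switch(format,
         csv = write_recording_csv(record, path),
         edf = write_recording_edf(record, path),
         rds = saveRDS(record, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "edf", "rds")) return(ext)
  stop("cannot guess format from extension '", ext, "'; pass `format`")
}

read_recording_csv <- function(path, fs) {
  first <- readLines(path, n = 1L)
  meta <- list(fs = fs, start_time = 0, strain = "SYNTHETIC")
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    for (kv in strsplit(sub("^#\\s*", "", first), "\\s+")[[1L]]) {
      p <- strsplit(kv, "=")[[1L]]
      if (length(p) == 2L) meta[[p[1L]]] <- p[2L]
    }
  }
  if (is.null(meta$fs)) stop("CSV has no fs metadata; supply `fs`")
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty CSV recording")
  dat <- unname(t(as.matrix(df)))
  signal_record(dat, fs = as.numeric(meta$fs),
                channel_sites = names(df),
                start_time = as.numeric(meta$start_time),
                strain_tag = meta$strain)
}

write_recording_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g start_time=%.10g strain=%s",
                     record$fs, record$start_time, record$strain_tag), con)
  df <- as.data.frame(t(record$data))
  names(df) <- record$channel_sites
  utils::write.csv(df, con, row.names = FALSE)
}

# --- minimal plain-EDF codec (16-bit little endian) ------------------------
# Plain EDF: 256-byte fixed header, 256 bytes per signal, then data records
# of 2-byte integers. The whole recording is stored as a single data record
# whose duration is n_samples / fs, which plain EDF permits and which keeps
# the round trip free of zero padding.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = -width)
}

# numeric header field: most compact representation that fits the width
num_field <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), format = "fg", width = 1, digits = d)
    if (nchar(s) <= width) return(pad_field(s, width))
  }
  stop("cannot represent ", x, " in ", width, " characters")
}

write_recording_edf <- function(record, path) {
  nch <- nrow(record$data); nsamp <- ncol(record$data)
  dur <- nsamp / record$fs
  dur_str <- formatC(dur, format = "fg", digits = 7, width = 1)
  if (nchar(dur_str) > 8) dur_str <- substr(dur_str, 1, 8)
  phys_max <- pmax(apply(abs(record$data), 1L, max), 1)
  phys_max <- signif(phys_max * 1.001, 6)  # keep extremes inside range
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(paste("Startdate 01-JAN-2000 strain", record$strain_tag), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (1L + nch), 8),
    pad_field("", 44),
    pad_field(1L, 8),
    pad_field(dur_str, 8),
    pad_field(nch, 4))
  sig <- paste0(
    paste(vapply(record$channel_sites, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field("uV", 8), nch), collapse = ""),
    paste(vapply(-phys_max, num_field, ""), collapse = ""),
    paste(vapply(phys_max, num_field, ""), collapse = ""),
    paste(rep(pad_field(-32767L, 8), nch), collapse = ""),
    paste(rep(pad_field(32767L, 8), nch), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field(nsamp, 8), nch), collapse = ""),
    paste(rep(pad_field("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  for (c_i in seq_len(nch)) {
    dig <- as.integer(round(record$data[c_i, ] / phys_max[c_i] * 32767))
    writeBin(dig, con, size = 2L, endian = "little")
  }
}

read_recording_edf <- function(path, site_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80)
  recording_id <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(trimws(rd(4)))
  if (is.na(nch) || nch < 1L) stop("malformed EDF header")
  labels <- trimws(vapply(seq_len(nch), function(i) rd(16), ""))
  for (i in seq_len(nch)) rd(80)                       # transducer
  dims <- trimws(vapply(seq_len(nch), function(i) rd(8), ""))
  phys_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)                       # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr / rec_dur)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1L] / rec_dur
  dat <- matrix(0, nrow = nch, ncol = spr[1L] * n_records)
  for (r in seq_len(n_records)) {
    for (c_i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[c_i], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(dig) != spr[c_i]) stop("truncated EDF data record")
      gain <- (phys_max[c_i] - phys_min[c_i]) / (dig_max[c_i] - dig_min[c_i])
      dat[c_i, (r - 1L) * spr[c_i] + seq_len(spr[c_i])] <-
        phys_min[c_i] + (dig - dig_min[c_i]) * gain
    }
  }
  if (!is.null(site_map)) {
    mapped <- site_map[labels]
    labels <- ifelse(is.na(mapped), labels, mapped)
  }
  labels[!(labels %in% swd_sites())] <- "OTHER"
  strain <- "SYNTHETIC"
  for (s in c("GAERS", "WAGRij")) if (grepl(s, recording_id)) strain <- s
  suppressWarnings(signal_record(dat, fs = fs, channel_sites = labels,
                                 strain_tag = strain))
}

#' Band-pass and notch filtering of a recording
#'
#' Applies the acquisition-style filtering (high pass, low pass, power-line
#' notch) as zero-phase Butterworth filters (forward-backward,
#' [signal::filtfilt()]), so event times are not shifted by filter delay.
#' The original hardware filtering was causal; the zero-phase choice is
#' deliberate so that onset marking and preictal labeling stay aligned with
#' the raw timeline.
#'
#' @param record a [signal_record()].
#' @param hp_hz high-pass corner (Hz), default 1; `NA` to skip.
#' @param lp_hz low-pass corner (Hz), default 100; `NA` to skip.
#' @param notch_hz notch centre (Hz), default 50 (set `NA` to skip); the stop
#'   band spans `notch_hz` +/- 2 Hz.
#' @return A filtered copy of `record`.
#' @export
preprocess_filter <- function(record, hp_hz = 1, lp_hz = 100, notch_hz = 50) {
  stopifnot(inherits(record, "SignalRecord"))
  nyq <- record$fs / 2
  if (!is.na(lp_hz) && lp_hz >= nyq)
    stop("`lp_hz` must be below the Nyquist frequency (", nyq, " Hz)")
  if (!is.na(hp_hz) && !is.na(lp_hz) && hp_hz >= lp_hz)
    stop("`hp_hz` must be below `lp_hz`")
  out <- record$data
  apply_filt <- function(filt, x) {
    for (i in seq_len(nrow(x))) x[i, ] <- signal::filtfilt(filt, x[i, ])
    x
  }
  if (!is.na(hp_hz))
    out <- apply_filt(signal::butter(2, hp_hz / nyq, type = "high"), out)
  if (!is.na(lp_hz))
    out <- apply_filt(signal::butter(4, lp_hz / nyq, type = "low"), out)
  if (!is.na(notch_hz)) {
    if (notch_hz + 2 >= nyq) stop("notch band must lie below Nyquist")
    out <- apply_filt(signal::butter(2, c(notch_hz - 2, notch_hz + 2) / nyq,
                                     type = "stop"), out)
  }
  record$data <- out
  record
}
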
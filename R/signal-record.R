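#' Recording-site vocabulary
#'
#' Controlled vocabulary of recording-site labels used throughout the package.
#' `S1_L4`, `S1_L5`, `S1_L6` are the deep layers (IV, V, VI) of the primary
#' somatosensory cortex; `VPM`, `Po`, `ATN`, `rRTN`, `cRTN` are thalamic
#' nuclei (ventral-postero-medial, posterior, anterior, rostral and caudal
#' reticular); `M2_5a`, `M2_5b`, `M2_6` are layers Va, Vb and VI of the
#' secondary motor cortex. Channels whose label is not in the vocabulary are
#' tagged `OTHER` and excluded from site-combination sweeps.
#'
#' @return Character vector of valid site labels.
#' @export
swd_sites <- function() {
  c("S1_L4", "S1_L5", "S1_L6",
    "VPM", "Po", "ATN", "rRTN", "cRTN",
    "M2_5a", "M2_5b", "M2_6", "OTHER")
}

#' Site class of a recording-site label
#'
#' Maps each site label to its anatomical class used for grouping site
#' combinations: `"C"` for S1 cortex, `"T"` for thalamic nuclei, `"M"` for
#' secondary motor cortex, `NA` for `OTHER`.
#'
#' @param sites character vector of site labels.
#' @return Character vector of classes ("C", "T", "M" or NA).
#' @export
site_class <- function(sites) {
  cls <- rep(NA_character_, length(sites))
  cls[sites %in% c("S1_L4", "S1_L5", "S1_L6")] <- "C"
  cls[sites %in% c("VPM", "Po", "ATN", "rRTN", "cRTN")] <- "T"
  cls[sites %in% c("M2_5a", "M2_5b", "M2_6")] <- "M"
  cls
}

#' Construct a multichannel LFP/EEG recording
#'
#' A `SignalRecord` holds a channels-by-samples matrix of amplitudes in
#' microvolts together with its sampling rate and per-channel recording-site
#' labels.
#'
#' @param data numeric matrix, channels x samples, amplitudes in microvolts.
#'   A vector is treated as a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_sites character vector of site labels, one per channel
#'   (see [swd_sites()]); labels outside the vocabulary are coerced to
#'   `"OTHER"` with a warning.
#' @param start_time offset of the first sample in seconds (default 0).
#' @param strain_tag one of `"GAERS"`, `"WAGRij"`, `"SYNTHETIC"`.
#' @return An object of class `SignalRecord`.
#' @export
signal_record <- function(data, fs, channel_sites,
                          start_time = 0,
                          strain_tag = c("SYNTHETIC", "GAERS", "WAGRij")) {
  strain_tag <- match.arg(strain_tag)
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(data)))
    stop("`data` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  channel_sites <- as.character(channel_sites)
  if (length(channel_sites) != nrow(data))
    stop("`channel_sites` must have one label per channel (", nrow(data), ")")
  bad <- !(channel_sites %in% swd_sites())
  if (any(bad)) {
    warning("unknown site label(s) ", paste(unique(channel_sites[bad]), collapse = ", "),
            " tagged OTHER")
    channel_sites[bad] <- "OTHER"
  }
  structure(
    list(data = data, fs = fs, channel_sites = channel_sites,
         start_time = start_time, strain_tag = strain_tag),
    class = "SignalRecord")
}

#' @export
print.SignalRecord <- function(x, ...) {
  cat(sprintf("SignalRecord: %d channel(s) x %d samples @ %g Hz (%.1f s), strain %s\n",
              nrow(x$data), ncol(x$data), x$fs, record_duration(x), x$strain_tag))
  cat("  sites:", paste(x$channel_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param record a [signal_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "SignalRecord"))
  ncol(record$data) / record$fs
}

#' Time axis of a recording
#' @param record a [signal_record()].
#' @return Numeric vector, time in seconds of each sample (0-based from
#'   `start_time`).
#' @export
record_times <- function(record) {
  record$start_time + (seq_len(ncol(record$data)) - 1L) / record$fs
}

#' Construct a seizure annotation
#'
#' Holds SWD onset/offset times in seconds from record start. The onset
#' convention is the peak of the first spike reaching twice the amplitude of
#' the background signal.
#'
#' @param onset_s numeric vector of onsets (seconds).
#' @param offset_s numeric vector of offsets (seconds), same length.
#' @return An object of class `SeizureAnnotation` (data frame with columns
#'   `onset_s`, `offset_s`).
#' @export
seizure_annotation <- function(onset_s = numeric(), offset_s = numeric()) {
  if (length(onset_s) != length(offset_s))
    stop("`onset_s` and `offset_s` must have equal length")
  if (any(offset_s <= onset_s))
    stop("each offset must exceed its onset")
  o <- order(onset_s)
  onset_s <- onset_s[o]; offset_s <- offset_s[o]
  if (length(onset_s) > 1L && any(onset_s[-1L] < offset_s[-length(offset_s)]))
    stop("events must be non-overlapping")
  structure(
    data.frame(onset_s = onset_s, offset_s = offset_s),
    onset_convention = "first_spike_peak_2x_background",
    class = c("SeizureAnnotation", "data.frame"))
}

#' Read/write a seizure annotation CSV
#'
#' Sidecar CSV with columns `onset_s`, `offset_s`, one row per SWD.
#'
#' @param path file path.
#' @return `read_annotation` returns a [seizure_annotation()];
#'   `write_annotation` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(df)))
    stop("annotation CSV must have columns onset_s, offset_s")
  seizure_annotation(df$onset_s, df$offset_s)
}

#' @rdname read_annotation
#' @param annotation a [seizure_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  utils::write.csv(as.data.frame(annotation)[, c("onset_s", "offset_s")],
                   path, row.names = FALSE)
  invisible(path)
}
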
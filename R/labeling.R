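#' Labeling configuration
#'
#' @param preictal_window_s length of the preictal window before SWD onset
#'   within which a detection counts as a true positive (default 1 s; the
#'   window is closed at the onset, so a detection exactly at onset is a
#'   true positive with zero prediction latency).
#' @param background_window_s artifact-free segment before each event used
#'   to estimate the background amplitude (default 10 s).
#' @param background_stat statistic of the background window; `"p99_abs"`
#'   (99th percentile of the absolute signal) is the only implemented
#'   choice.
#' @param onset_multiplier the first spike reaching this multiple of the
#'   background amplitude marks the onset (default 2).
#' @return list of class `LabelingConfig`.
#' @export
labeling_config <- function(preictal_window_s = 1.0,
                            background_window_s = 10,
                            background_stat = "p99_abs",
                            onset_multiplier = 2.0) {
  if (preictal_window_s <= 0) stop("`preictal_window_s` must be positive")
  if (onset_multiplier <= 1) stop("`onset_multiplier` must exceed 1")
  background_stat <- match.arg(background_stat, "p99_abs")
  structure(list(preictal_window_s = preictal_window_s,
                 background_window_s = background_window_s,
                 background_stat = background_stat,
                 onset_multiplier = onset_multiplier),
            class = "LabelingConfig")
}

#' Mark SWD onsets by the first-spike amplitude rule
#'
#' For each coarse event and channel, the background amplitude is the 99th
#' percentile of the absolute signal over the background window preceding
#' the event (shrunk, with a warning, if it would overlap the previous
#' event; an error if less than 1 s remains). The onset candidate of a
#' channel is the time of the first local extremum within the coarse event
#' whose absolute amplitude reaches `onset_multiplier` times the background
#' amplitude; across channels the earliest candidate wins (spike timing
#' differs by milliseconds between sites). Events in which no channel has a
#' qualifying spike are dropped with a warning.
#'
#' @param record a [signal_record()].
#' @param coarse_events data.frame (or 2-column matrix) of approximate
#'   `start_s`, `end_s` in seconds.
#' @param config a [labeling_config()].
#' @return A [seizure_annotation()] with the refined onsets.
#' @export
mark_swd_onsets <- function(record, coarse_events, config = labeling_config()) {
  stopifnot(inherits(record, "SignalRecord"))
  ce <- as.data.frame(coarse_events)
  names(ce)[1:2] <- c("start_s", "end_s")
  ce <- ce[order(ce$start_s), , drop = FALSE]
  fs <- record$fs
  n <- ncol(record$data)
  dur <- record_duration(record)
  if (any(ce$start_s < 0 | ce$end_s > dur | ce$start_s >= ce$end_s))
    stop("coarse events must lie within the record")
  onsets <- numeric(0); offsets <- numeric(0)
  prev_end <- -Inf
  for (e in seq_len(nrow(ce))) {
    bg_start <- ce$start_s[e] - config$background_window_s
    if (bg_start < prev_end) {
      warning("background window shrunk to avoid the previous event")
      bg_start <- prev_end
    }
    bg_start <- max(bg_start, 0)
    if (ce$start_s[e] - bg_start < 1)
      stop("less than 1 s of background available before event ", e)
    bg_idx <- (floor(bg_start * fs) + 1L):floor(ce$start_s[e] * fs)
    ev_idx <- (floor(ce$start_s[e] * fs) + 1L):min(n, ceiling(ce$end_s[e] * fs))
    best <- Inf
    for (c_i in seq_len(nrow(record$data))) {
      x_bg <- record$data[c_i, bg_idx]
      bg_amp <- stats::quantile(abs(x_bg), 0.99, names = FALSE)
      x <- record$data[c_i, ev_idx]
      d <- diff(x)
      ext <- which(d[-length(d)] * d[-1L] < 0) + 1L  # local extrema
      qual <- ext[abs(x[ext]) >= config$onset_multiplier * bg_amp]
      if (length(qual)) {
        t_cand <- (ev_idx[qual[1L]] - 1L) / fs
        if (t_cand < best) best <- t_cand
      }
    }
    if (is.finite(best)) {
      onsets <- c(onsets, best)
      offsets <- c(offsets, ce$end_s[e])
    } else {
      warning("event ", e, " has no spike reaching ",
              config$onset_multiplier, "x background; dropped")
    }
    prev_end <- ce$end_s[e]  # dropped events still contaminate the background
  }
  seizure_annotation(onsets, offsets)
}

#' Label detections against the preictal windows
#'
#' A detection at time `t` is a true positive if `t` falls within the
#' preictal window `[onset - w, onset]` of an SWD, an ictal discard if it
#' falls inside the SWD itself (`(onset, offset]`; such detections are
#' neither true nor false positives), and a false positive otherwise. An
#' SWD counts as predicted if at least one true positive falls in its
#' window; extra detections in the same window keep the TP label but the
#' SWD is counted once.
#'
#' @param events a [detect_events()] data.frame (any data.frame with a `t`
#'   column works).
#' @param annotation a [seizure_annotation()].
#' @param config a [labeling_config()].
#' @return list with `events` (the input with `label` and `swd_index`
#'   columns filled) and `counts` (list `n_swd`, `n_tp_swd` SWDs predicted,
#'   `n_missed`, `n_tp_events`, `n_fp`, `n_discarded`).
#' @export
label_detections <- function(events, annotation, config = labeling_config()) {
  stopifnot(is.data.frame(events))
  if (nrow(annotation) > 1L && is.unsorted(annotation$onset_s))
    stop("annotation must be sorted by onset")
  w <- config$preictal_window_s
  lab <- rep("FP", nrow(events))
  swd_index <- rep(NA_integer_, nrow(events))
  for (i in seq_len(nrow(events))) {
    t <- events$t[i]
    hit <- which(t >= annotation$onset_s - w & t <= annotation$onset_s)
    if (length(hit)) {
      lab[i] <- "TP"; swd_index[i] <- hit[1L]
    } else if (any(t > annotation$onset_s & t <= annotation$offset_s)) {
      lab[i] <- "ICTAL_DISCARD"
    }
  }
  events$label <- lab
  events$swd_index <- swd_index
  counts <- list(n_swd = nrow(annotation),
                 n_tp_swd = length(unique(swd_index[!is.na(swd_index)])),
                 n_tp_events = sum(lab == "TP"),
                 n_fp = sum(lab == "FP"),
                 n_discarded = sum(lab == "ICTAL_DISCARD"))
  counts$n_missed <- counts$n_swd - counts$n_tp_swd
  list(events = events, counts = counts)
}
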
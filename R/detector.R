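#' Detector configuration
#'
#' @param threshold detection threshold on the precursor-band product (> 0).
#' @param refractory_s merge window: super-threshold runs separated by less
#'   than this many seconds count as one detection event (default 1.0 s).
#' @param bands a [band_defs()].
#' @return list of class `DetectorConfig`.
#' @export
detector_config <- function(threshold = 0.1, refractory_s = 1.0,
                            bands = band_defs()) {
  if (threshold <= 0) stop("`threshold` must be positive")
  if (refractory_s < 0) stop("`refractory_s` must be non-negative")
  structure(list(threshold = threshold, refractory_s = refractory_s,
                 bands = bands),
            class = "DetectorConfig")
}

#' Apply the three precursor criteria and extract detection events
#'
#' A time step is super-threshold iff the precursor-band product exceeds (1)
#' the detection threshold, (2) the slow-wave-sleep-band product, and (3)
#' the spindle-band product. Maximal super-threshold runs separated by less
#' than `refractory_s` are merged into one event, time-stamped at the run
#' start (the earliest evidence). Each event carries the per-channel,
#' per-band energies at its time stamp (the classifier features) and the
#' peak precursor-band product over the merged run (`peak`, used by
#' threshold sweeps).
#'
#' @param products a [channel_product()] series.
#' @param energies the [band_energy_series()] the products were built from.
#' @param config a [detector_config()].
#' @return data.frame of class `DetectionEvents` with columns `t`, `peak`,
#'   `start_idx`/`end_idx` (run extent, indices into the product series),
#'   one `W_<band>_<site>` column per feature, and `label` (initially
#'   `"UNLABELED"`).
#' @export
detect_events <- function(products, energies, config = detector_config()) {
  stopifnot(inherits(products, "ProductSeries"),
            inherits(energies, "BandEnergySeries"),
            inherits(config, "DetectorConfig"))
  if (length(products$times) != length(energies$times) ||
      any(abs(products$times - energies$times) > 1e-9))
    stop("products and energies must share time stamps")
  P <- products$P
  mask <- P["precursor", ] > config$threshold &
    P["precursor", ] > P["sws", ] &
    P["precursor", ] > P["spindle", ]
  ev <- mask_to_events(mask, products$times, P["precursor", ],
                       config$refractory_s)
  feats <- event_features(energies, products$channels, ev$start_idx)
  out <- cbind(data.frame(t = ev$t, peak = ev$peak,
                          start_idx = ev$start_idx, end_idx = ev$end_idx),
               feats)
  out$label <- rep("UNLABELED", nrow(out))
  structure(out, class = c("DetectionEvents", "data.frame"),
            channels = products$channels,
            feature_names = names(feats))
}

# Merge a logical mask into events: runs of TRUE, runs closer than
# refractory_s merged; returns start index, time and peak score per event.
mask_to_events <- function(mask, times, score, refractory_s) {
  if (!any(mask))
    return(list(start_idx = integer(0), end_idx = integer(0),
                t = numeric(0), peak = numeric(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  merged_s <- run_start[1L]; merged_e <- run_end[1L]
  out_s <- integer(0); out_e <- integer(0)
  if (length(run_start) > 1L) {
    for (k in 2L:length(run_start)) {
      if (times[run_start[k]] - times[merged_e] < refractory_s) {
        merged_e <- run_end[k]
      } else {
        out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
        merged_s <- run_start[k]; merged_e <- run_end[k]
      }
    }
  }
  out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
  peak <- vapply(seq_along(out_s),
                 function(k) max(score[out_s[k]:out_e[k]]), 0)
  list(start_idx = out_s, end_idx = out_e, t = times[out_s], peak = peak)
}

event_features <- function(energies, channels, idx) {
  ch_i <- match(channels, energies$channel_sites)
  bands <- rownames(energies$values)
  cols <- list()
  for (ci in seq_along(ch_i)) {
    for (b in bands) {
      nm <- paste0("W_", b, "_", channels[ci])
      cols[[nm]] <- if (length(idx))
        energies$values[b, ch_i[ci], idx] else numeric(0)
    }
  }
  as.data.frame(cols, optional = TRUE)
}

#' Enumerate recording-site combinations
#'
#' All combinations of two or three recording sites that belong to one of
#' the analysis groups: intracortical S1 pairs and triples (CC, CCC), mixed
#' cortico-thalamic sets (CT, CCT, CTT), intrathalamic sets (TT, TTT), and
#' the secondary-motor-cortex triple (MCCC). With the eight standard S1 +
#' thalamic sites and the three M2 sites this yields the canonical 57
#' three-site and 28 two-site combinations (85 in total); M2 sites only ever
#' appear as the complete M2 triple.
#'
#' @param available_sites character vector of distinct site labels.
#' @return data.frame with columns `site1`, `site2`, `site3` (`NA` for
#'   pairs), `n_sites`, `group`, `combination` (collapsed label).
#' @export
enumerate_site_combinations <- function(available_sites = setdiff(swd_sites(), "OTHER")) {
  sites <- available_sites
  if (anyDuplicated(sites)) stop("duplicate sites")
  cls <- site_class(sites)
  if (anyNA(cls)) stop("sites must come from the controlled vocabulary (no OTHER)")
  rows <- list()
  add <- function(ss) {
    cc <- sort(site_class(ss))
    key <- paste(cc, collapse = "")
    group <- switch(key,
                    CC = "CC", CT = "CT", TT = "TT",
                    CCC = "CCC", CCT = "CCT", CTT = "CTT", TTT = "TTT",
                    MMM = "MCCC",
                    NA_character_)
    if (is.na(group)) return(NULL)
    data.frame(site1 = ss[1], site2 = ss[2],
               site3 = if (length(ss) == 3L) ss[3] else NA_character_,
               n_sites = length(ss), group = group,
               combination = paste(ss, collapse = "/"),
               stringsAsFactors = FALSE)
  }
  if (length(sites) >= 2L) {
    prs <- utils::combn(sites, 2L, simplify = FALSE)
    for (p in prs) rows[[length(rows) + 1L]] <- add(p)
  }
  if (length(sites) >= 3L) {
    tps <- utils::combn(sites, 3L, simplify = FALSE)
    for (p in tps) rows[[length(rows) + 1L]] <- add(p)
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(site1 = character(), site2 = character(),
                      site3 = character(), n_sites = integer(),
                      group = character(), combination = character()))
  do.call(rbind, rows)
}

#' Default detection-threshold grids
#'
#' 14 linearly spaced thresholds on `[0.1, 0.75]` for three-site products
#' and 16 on `[0.005, 0.04]` for two-site products.
#'
#' @param n_sites 2 or 3.
#' @return Numeric vector of thresholds.
#' @export
default_threshold_grid <- function(n_sites) {
  if (n_sites == 3L) seq(0.1, 0.75, length.out = 14L)
  else if (n_sites == 2L) seq(0.005, 0.04, length.out = 16L)
  else stop("`n_sites` must be 2 or 3")
}

# Detect at the smallest threshold of interest and label once; a detection
# episode then counts at threshold th iff its peak product exceeds th. This
# episode-level scoring makes sensitivity and false-alarm counts
# non-increasing in the threshold by construction (the same way a ROC curve
# is swept), while sharing one labeling pass across the whole grid. The
# score is the peak product over the episode's non-ictal samples: an
# episode that starts preictally and runs on into the seizure is scored by
# its preictal evidence, not by the (always enormous) ictal energy. The
# annotated onset is the peak of the first spike, whose rising edge is
# already seizure activity; `onset_guard_s` excludes that final fraction of
# a second from the score so thresholds discriminate precursor evidence,
# not the onset spike itself. The exclusion extends `postictal_guard_s`
# past each offset because the causal kernel and averaging window carry
# seizure energy forward by roughly their combined length. Episodes whose
# whole extent falls in the excluded zones are scored by the product at
# their start (essentially the threshold crossing).
scored_episodes <- function(record, annotation, combination, base_threshold,
                            energies = NULL, stride_s = NULL,
                            refractory_s = 1.0, onset_guard_s = 0.1,
                            postictal_guard_s = 2.0,
                            labeling = labeling_config(), ...) {
  sites <- combination_sites(combination)
  if (is.null(energies))
    energies <- band_energy_series(record, stride_s = stride_s,
                                   channels = sites, ...)
  prod <- channel_product(energies, sites)
  cfg <- detector_config(threshold = base_threshold,
                         refractory_s = refractory_s)
  events <- detect_events(prod, energies, cfg)
  events <- rescore_events(events, prod, energies, annotation,
                           onset_guard_s, postictal_guard_s)
  lab <- label_detections(events, annotation, labeling)
  lab$events
}

#' Score detection episodes by their strongest non-ictal evidence
#'
#' Replaces each episode's `peak` by the maximum precursor-band product over
#' its non-ictal samples and re-extracts the classifier features at the time
#' of that peak — the moment of strongest precursor evidence — instead of at
#' the threshold crossing, where true and false alarms look alike. Samples
#' from `onset_guard_s` before each annotated onset (the rising edge of the
#' first spike) to `postictal_guard_s` after each offset (the causal
#' analysis memory) do not count as evidence; episodes lying entirely in
#' those zones keep the product at their start.
#'
#' @param events a [detect_events()] result.
#' @param prod the [channel_product()] series the events came from.
#' @param energies the matching [band_energy_series()].
#' @param annotation a [seizure_annotation()].
#' @param onset_guard_s seconds before each onset excluded from evidence.
#' @param postictal_guard_s seconds after each offset excluded from
#'   evidence.
#' @return `events` with updated `peak` and feature columns.
#' @export
rescore_events <- function(events, prod, energies, annotation,
                           onset_guard_s = 0.1, postictal_guard_s = 2.0) {
  if (!nrow(events)) return(events)
  score <- prod$P["precursor", ]
  ictal <- rep(FALSE, length(prod$times))
  for (e in seq_len(nrow(annotation)))
    ictal <- ictal | (prod$times > annotation$onset_s[e] - onset_guard_s &
                        prod$times <= annotation$offset_s[e] + postictal_guard_s)
  peak_idx <- integer(nrow(events))
  for (k in seq_len(nrow(events))) {
    idx <- events$start_idx[k]:events$end_idx[k]
    idx <- idx[!ictal[idx]]
    peak_idx[k] <- if (length(idx)) idx[which.max(score[idx])] else
      events$start_idx[k]
  }
  events$peak <- score[peak_idx]
  feats <- event_features(energies, prod$channels, peak_idx)
  events[names(feats)] <- feats
  events
}

combination_sites <- function(combination) {
  if (is.data.frame(combination)) {
    stopifnot(nrow(combination) == 1L)
    sites <- c(combination$site1, combination$site2, combination$site3)
    sites <- sites[!is.na(sites)]
  } else {
    sites <- as.character(combination)
  }
  if (!(length(sites) %in% c(2L, 3L)))
    stop("a combination has 2 or 3 sites")
  sites
}

#' Sweep detection thresholds for one site combination
#'
#' Runs detection, labeling and the prediction metrics for every threshold
#' of the grid. Episodes are detected once at the smallest grid threshold;
#' each episode counts at a threshold iff its peak precursor product exceeds
#' it, so sensitivity and the false-alarm count are non-increasing along the
#' grid.
#'
#' @param record a [signal_record()].
#' @param annotation a [seizure_annotation()].
#' @param combination character vector of 2-3 site labels, or one row of
#'   [enumerate_site_combinations()].
#' @param grid threshold grid; default [default_threshold_grid()] for the
#'   combination size.
#' @param energies optional precomputed [band_energy_series()] (saves the
#'   wavelet transform when sweeping many combinations of one recording).
#' @param stride_s stride passed to [band_energy_series()] when `energies`
#'   is not supplied.
#' @param refractory_s event merge window (s).
#' @param labeling a [labeling_config()].
#' @param ... further arguments to [band_energy_series()].
#' @return data.frame of class `SweepResult`: one row per threshold with
#'   `combination`, `group`, `n_sites`, `threshold`, `sensitivity_pct`,
#'   `fp_per_h`, `n_tp`, `n_fp`, `n_swd`.
#' @export
sweep_thresholds <- function(record, annotation, combination, grid = NULL,
                             energies = NULL, stride_s = NULL,
                             refractory_s = 1.0,
                             labeling = labeling_config(), ...) {
  sites <- combination_sites(combination)
  if (is.null(grid)) grid <- default_threshold_grid(length(sites))
  if (length(grid) == 0L || any(grid <= 0)) stop("grid must be non-empty and positive")
  grid <- sort(grid)
  ev <- scored_episodes(record, annotation, combination = sites,
                        base_threshold = min(grid), energies = energies,
                        stride_s = stride_s, refractory_s = refractory_s,
                        labeling = labeling, ...)
  hours <- record_duration(record) / 3600
  n_swd <- nrow(annotation)
  grp <- combination_group(sites)
  rows <- lapply(grid, function(th) {
    keep <- ev$peak > th
    tp_keep <- keep & ev$label == "TP"
    n_pred <- length(unique(ev$swd_index[tp_keep]))
    n_fp <- sum(keep & ev$label == "FP")
    sens <- if (n_swd > 0) 100 * n_pred / n_swd else NA_real_
    data.frame(combination = paste(sites, collapse = "/"), group = grp,
               n_sites = length(sites), threshold = th,
               sensitivity_pct = sens, fp_per_h = n_fp / hours,
               n_tp = sum(tp_keep), n_fp = n_fp, n_swd = n_swd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("SweepResult", "data.frame")
  out
}

combination_group <- function(sites) {
  key <- paste(sort(site_class(sites)), collapse = "")
  switch(key, CC = "CC", CT = "CT", TT = "TT", CCC = "CCC", CCT = "CCT",
         CTT = "CTT", TTT = "TTT", MMM = "MCCC", NA_character_)
}

#' Calibrate the detection threshold to a target sensitivity
#'
#' Finds, by bisection, the largest threshold whose achieved sensitivity is
#' still at or above the target (the individualised threshold of the
#' algorithm: ties resolve to the larger threshold). If even the smallest
#' grid threshold cannot reach the target, that threshold is returned with a
#' warning and `flagged = TRUE`.
#'
#' @inheritParams sweep_thresholds
#' @param target_sensitivity_pct target sensitivity in percent, in (0, 100].
#' @param floor_threshold smallest admissible threshold; defaults to the
#'   minimum of the default grid for the combination size.
#' @return list with `threshold`, `achieved_sensitivity_pct`, `flagged`.
#' @export
calibrate_threshold <- function(record, annotation, combination,
                                target_sensitivity_pct = 90,
                                floor_threshold = NULL,
                                energies = NULL, stride_s = NULL,
                                refractory_s = 1.0,
                                labeling = labeling_config(), ...) {
  if (target_sensitivity_pct <= 0 || target_sensitivity_pct > 100)
    stop("`target_sensitivity_pct` must be in (0, 100]")
  if (nrow(annotation) < 5L)
    stop("calibration requires at least 5 annotated SWDs")
  sites <- combination_sites(combination)
  if (is.null(floor_threshold))
    floor_threshold <- min(default_threshold_grid(length(sites)))
  ev <- scored_episodes(record, annotation, combination = sites,
                        base_threshold = floor_threshold, energies = energies,
                        stride_s = stride_s, refractory_s = refractory_s,
                        labeling = labeling, ...)
  n_swd <- nrow(annotation)
  sens_at <- function(th) {
    keep <- ev$peak > th & ev$label == "TP"
    100 * length(unique(ev$swd_index[keep])) / n_swd
  }
  if (sens_at(floor_threshold) < target_sensitivity_pct) {
    warning("target sensitivity unreachable; returning the floor threshold")
    return(list(threshold = floor_threshold,
                achieved_sensitivity_pct = sens_at(floor_threshold),
                flagged = TRUE))
  }
  lo <- floor_threshold
  hi <- max(ev$peak, floor_threshold) * 1.01
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sens_at(mid) >= target_sensitivity_pct) lo <- mid else hi <- mid
  }
  list(threshold = lo, achieved_sensitivity_pct = sens_at(lo),
       flagged = FALSE)
}
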
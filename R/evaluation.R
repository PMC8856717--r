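#' Sensitivity and false-alarm rate of SWD prediction
#'
#' Sensitivity is the percentage of SWDs correctly predicted,
#' `100 * n_predicted / (n_predicted + n_unpredicted)`; the false-alarm rate
#' is the number of false positives per analysed recording hour (the
#' denominator is total recording time, not interictal time only).
#'
#' @param n_predicted_swds number of correctly predicted SWDs.
#' @param n_unpredicted_swds number of unpredicted SWDs.
#' @param n_fp number of false positives.
#' @param hours analysed recording duration in hours.
#' @return list with `sensitivity_pct` (full precision; round for display)
#'   and `fp_per_h`.
#' @export
prediction_metrics <- function(n_predicted_swds, n_unpredicted_swds, n_fp,
                               hours) {
  if (any(c(n_predicted_swds, n_unpredicted_swds, n_fp) < 0))
    stop("counts must be non-negative")
  if (hours <= 0) stop("`hours` must be positive")
  n_swd <- n_predicted_swds + n_unpredicted_swds
  if (n_swd == 0) stop("sensitivity undefined without SWDs")
  list(sensitivity_pct = 100 * n_predicted_swds / n_swd,
       fp_per_h = n_fp / hours)
}

#' Construct a classification confusion matrix
#'
#' Counts of detection events by true class (TP or FP detection) and
#' predicted class.
#'
#' @param tp_as_tp true positives classified as true positives.
#' @param tp_as_fp true positives classified as false positives.
#' @param fp_as_fp false positives classified as false positives.
#' @param fp_as_tp false positives classified as true positives.
#' @return list of class `ConfusionMatrix`.
#' @export
confusion_matrix <- function(tp_as_tp, tp_as_fp, fp_as_fp, fp_as_tp) {
  v <- c(tp_as_tp, tp_as_fp, fp_as_fp, fp_as_tp)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(list(tp_as_tp = tp_as_tp, tp_as_fp = tp_as_fp,
                 fp_as_fp = fp_as_fp, fp_as_tp = fp_as_tp),
            class = "ConfusionMatrix")
}

#' Classification performance metrics
#'
#' Sensitivity (of classification) is the fraction of true-positive
#' detections classified as such; specificity the fraction of
#' false-positive detections classified as such; balanced accuracy their
#' mean; precision the fraction of predicted true positives that are true
#' positives; `F1 = 2 * precision * sensitivity / (precision +
#' sensitivity)`, defined as 0 when both are 0. All returned in percent.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `balanced_accuracy_pct`, `f1_pct`, `sensitivity_pct`,
#'   `specificity_pct`, `precision_pct`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "ConfusionMatrix"))
  n_tp <- cm$tp_as_tp + cm$tp_as_fp
  n_fp <- cm$fp_as_fp + cm$fp_as_tp
  if (n_tp == 0 || n_fp == 0)
    stop("both classes must be present in the confusion matrix")
  sens <- cm$tp_as_tp / n_tp
  spec <- cm$fp_as_fp / n_fp
  prec <- if (cm$tp_as_tp + cm$fp_as_tp > 0)
    cm$tp_as_tp / (cm$tp_as_tp + cm$fp_as_tp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(balanced_accuracy_pct = 100 * (sens + spec) / 2,
       f1_pct = 100 * f1,
       sensitivity_pct = 100 * sens,
       specificity_pct = 100 * spec,
       precision_pct = 100 * prec)
}

#' Group-level summary of a threshold/site sweep
#'
#' Averages sensitivity and false-alarm rate over thresholds within each
#' site combination, then summarises each anatomical group (CC, CT, TT,
#' CCC, CCT, CTT, TTT, MCCC) by the mean and standard error over its
#' combinations. Purely descriptive; the per-row sweep table is retained
#' for any inferential analysis.
#'
#' @param sweep a [sweep_thresholds()] result (rows from several
#'   combinations may be concatenated with `rbind`).
#' @return data.frame with one row per non-empty group: `group`,
#'   `n_combinations`, `mean_sensitivity_pct`, `sem_sensitivity_pct`,
#'   `mean_fp_per_h`, `sem_fp_per_h`.
#' @export
group_combinations <- function(sweep) {
  stopifnot(is.data.frame(sweep), nrow(sweep) > 0)
  if (any(is.na(sweep$group)) || !all(sweep$group %in%
        c("CC", "CT", "TT", "CCC", "CCT", "CTT", "TTT", "MCCC")))
    stop("unknown group tag in sweep")
  per_comb <- stats::aggregate(
    cbind(sensitivity_pct, fp_per_h) ~ combination + group, data = sweep,
    FUN = mean)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- do.call(rbind, lapply(split(per_comb, per_comb$group), function(d) {
    data.frame(group = d$group[1L], n_combinations = nrow(d),
               mean_sensitivity_pct = mean(d$sensitivity_pct),
               sem_sensitivity_pct = sem(d$sensitivity_pct),
               mean_fp_per_h = mean(d$fp_per_h),
               sem_fp_per_h = sem(d$fp_per_h),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between prediction sensitivity and false-alarm rate
#'
#' Pearson product-moment correlation between the per-combination mean
#' sensitivity and mean false-alarm rate, with the two-sided p value.
#'
#' @param sweep a sweep table covering at least 3 combinations.
#' @return list with `r`, `p_value`, `n` (number of combinations).
#' @export
sens_fp_correlation <- function(sweep) {
  stopifnot(is.data.frame(sweep))
  per_comb <- stats::aggregate(
    cbind(sensitivity_pct, fp_per_h) ~ combination, data = sweep, FUN = mean)
  if (nrow(per_comb) < 3L) stop("at least 3 combinations required")
  if (stats::sd(per_comb$sensitivity_pct) == 0 ||
      stats::sd(per_comb$fp_per_h) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(per_comb$sensitivity_pct, per_comb$fp_per_h,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(per_comb))
}

#' Wavelet-energy summary of true versus false positives
#'
#' Compares the per-band wavelet energies of all true-positive detections
#' with a random sample of false positives (default 50, sampled without
#' replacement under the given seed; if fewer are available all are used
#' with a warning). Per event, the band energy is averaged over the
#' combination's channels.
#'
#' @param events labeled detection events (from [label_detections()]).
#' @param n_fp_sample number of false positives to sample.
#' @param rng_seed integer seed for the sampling.
#' @return data.frame with one row per band and class: `band`, `class`,
#'   `n`, `mean_energy`, `sem_energy`.
#' @export
tp_fp_energy_summary <- function(events, n_fp_sample = 50, rng_seed = 1) {
  stopifnot(is.data.frame(events))
  tp <- events[events$label == "TP", , drop = FALSE]
  fp <- events[events$label == "FP", , drop = FALSE]
  if (nrow(tp) < 1L) stop("at least one true positive required")
  if (nrow(fp) < n_fp_sample) {
    warning("fewer false positives than requested; using all ", nrow(fp))
  } else {
    set.seed(rng_seed)
    fp <- fp[sort(sample.int(nrow(fp), n_fp_sample)), , drop = FALSE]
  }
  fcols <- grep("^W_", names(events), value = TRUE)
  bands <- unique(sub("^W_([^_]+)_.*$", "\\1", fcols))
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  rows <- list()
  for (b in bands) {
    bc <- grep(paste0("^W_", b, "_"), names(events), value = TRUE)
    for (cls in c("TP", "FP")) {
      d <- if (cls == "TP") tp else fp
      v <- rowMeans(d[, bc, drop = FALSE])
      rows[[paste(b, cls)]] <- data.frame(
        band = b, class = cls, n = length(v),
        mean_energy = mean(v), sem_energy = sem(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
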
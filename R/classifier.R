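#' Sampling plan for class balancing
#'
#' True-positive detections are heavily outnumbered by false positives, so
#' training sets are balanced either by undersampling the false positives
#' (all TPs plus an equal number of randomly drawn FPs) or by moderate
#' oversampling (the TP set replicated `oversample_factor` times, matched
#' by the same number of randomly drawn FPs; the default factor 4 was the
#' best of the admissible range 2-7, higher factors risking overtraining).
#'
#' @param mode `"undersample"` or `"oversample"`.
#' @param oversample_factor integer >= 2 (oversampling only; admissible
#'   2-7).
#' @param rng_seed integer seed for the FP draw.
#' @return list of class `SamplingPlan`.
#' @export
sampling_plan <- function(mode = c("undersample", "oversample"),
                          oversample_factor = 4, rng_seed = 1) {
  mode <- match.arg(mode)
  if (mode == "oversample" && oversample_factor < 2)
    stop("oversampling requires a factor of at least 2")
  if (oversample_factor < 1) stop("factor must be >= 1")
  structure(list(mode = mode, oversample_factor = oversample_factor,
                 rng_seed = rng_seed),
            class = "SamplingPlan")
}

#' Extract the feature table from labeled detection events
#'
#' Keeps TP- and FP-labeled events (ictal discards and unlabeled events are
#' dropped) and collects their per-channel, per-band wavelet energies (6 or
#' 9 features) into a matrix.
#'
#' @param events labeled detection events.
#' @return list of class `FeatureTable` with `X` (matrix), `y` (factor
#'   FP/TP), `t` (event times).
#' @export
feature_table <- function(events) {
  stopifnot(is.data.frame(events))
  keep <- events$label %in% c("TP", "FP")
  ev <- events[keep, , drop = FALSE]
  fcols <- grep("^W_", names(ev), value = TRUE)
  if (!(length(fcols) %in% c(6L, 9L)))
    stop("expected 6 or 9 wavelet-energy features, got ", length(fcols))
  X <- as.matrix(ev[, fcols, drop = FALSE])
  if (anyNA(X) || any(X < 0)) stop("features must be non-negative and complete")
  structure(list(X = X, y = factor(ev$label, levels = c("FP", "TP")),
                 t = ev$t),
            class = "FeatureTable")
}

#' Chronological train/evaluation split of detection events
#'
#' The first `frac` of the recording (by time) is the training period, the
#' rest the in-sample evaluation period — a pseudo-prospective split: every
#' training event precedes every evaluation event.
#'
#' @param events labeled detection events.
#' @param duration_s recording duration in seconds.
#' @param frac training fraction (default 0.7).
#' @param start_time recording start time (s).
#' @return list with `train` and `eval` event data.frames.
#' @export
split_events_chronological <- function(events, duration_s, frac = 0.7,
                                       start_time = 0) {
  stopifnot(is.data.frame(events), frac > 0, frac < 1)
  cut <- start_time + frac * duration_s
  list(train = events[events$t <= cut, , drop = FALSE],
       eval = events[events$t > cut, , drop = FALSE])
}

#' Build a balanced training set
#'
#' Undersampling keeps every TP and draws an equal number of FPs without
#' replacement; oversampling replicates the TP set `oversample_factor`
#' times and draws `factor * n_TP` FPs without replacement. Class counts
#' are exactly equal either way.
#'
#' @param events labeled detection events (training period).
#' @param plan a [sampling_plan()].
#' @return A [feature_table()] with balanced classes.
#' @export
build_balanced_training_set <- function(events, plan = sampling_plan()) {
  stopifnot(inherits(plan, "SamplingPlan"))
  tab <- feature_table(events)
  tp_i <- which(tab$y == "TP")
  fp_i <- which(tab$y == "FP")
  if (length(tp_i) < 5L)
    stop("at least 5 true positives required for training")
  k <- if (plan$mode == "undersample") 1L else as.integer(plan$oversample_factor)
  need_fp <- k * length(tp_i)
  if (length(fp_i) < need_fp)
    stop("false-positive pool too small: need ", need_fp, ", have ",
         length(fp_i))
  set.seed(plan$rng_seed)
  fp_sel <- sample(fp_i, need_fp)
  tp_sel <- rep(tp_i, k)
  sel <- c(tp_sel, fp_sel)
  structure(list(X = tab$X[sel, , drop = FALSE], y = tab$y[sel],
                 t = tab$t[sel]),
            class = "FeatureTable")
}

#' Train a majority-vote random forest
#'
#' Fits a random forest (default 1000 trees, `sqrt(d)` candidate features
#' per split, bootstrap resampling, unlimited depth) on the feature table.
#' Classification is by simple majority vote over the trees; vote ties (an
#' even forest splitting evenly) classify as FP, which conservatively
#' suppresses the alarm. Deterministic for a given seed.
#'
#' @param table a [feature_table()] with both classes present.
#' @param n_trees number of trees.
#' @param rng_seed integer seed.
#' @param mtry candidate features per split (default `floor(sqrt(d))`).
#' @param min_node_size minimal terminal node size (default 1).
#' @return object of class `swd_forest`.
#' @export
train_random_forest <- function(table, n_trees = 1000, rng_seed = 1,
                                mtry = NULL, min_node_size = 1) {
  stopifnot(inherits(table, "FeatureTable"))
  if (nlevels(droplevels(table$y)) < 2L)
    stop("both classes must be present for training")
  d <- ncol(table$X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(d)))
  df <- data.frame(.class = table$y, table$X, check.names = FALSE)
  rf <- ranger::ranger(dependent.variable.name = ".class", data = df,
                       num.trees = n_trees, mtry = mtry,
                       min.node.size = min_node_size,
                       replace = TRUE, seed = rng_seed, num.threads = 1L,
                       classification = TRUE)
  structure(list(rf = rf, n_trees = n_trees,
                 feature_names = colnames(table$X),
                 seed = rng_seed),
            class = "swd_forest")
}

#' @export
print.swd_forest <- function(x, ...) {
  cat(sprintf("swd_forest: %d trees, %d features (majority vote, ties -> FP)\n",
              x$n_trees, length(x$feature_names)))
  invisible(x)
}

#' Predict detection classes by majority vote
#'
#' @param object a [train_random_forest()] model (or, for testing and
#'   baselines, a function mapping a feature matrix to a character vector
#'   of `"TP"`/`"FP"`).
#' @param X feature matrix with the model's feature columns.
#' @param ... unused.
#' @return factor with levels FP/TP.
#' @export
predict_classes <- function(object, X, ...) {
  if (is.function(object)) {
    return(factor(object(X), levels = c("FP", "TP")))
  }
  stopifnot(inherits(object, "swd_forest"))
  if (!all(object$feature_names %in% colnames(X)))
    stop("feature dimension mismatch")
  X <- X[, object$feature_names, drop = FALSE]
  pr <- stats::predict(object$rf, data = as.data.frame(X),
                       predict.all = TRUE, num.threads = 1L)$predictions
  tp_code <- which(object$rf$forest$levels == "TP")
  votes_tp <- rowSums(pr == tp_code)
  factor(ifelse(votes_tp > object$n_trees / 2, "TP", "FP"),
         levels = c("FP", "TP"))
}

balanced_accuracy <- function(truth, pred) {
  truth <- factor(truth, levels = c("FP", "TP"))
  pred <- factor(pred, levels = c("FP", "TP"))
  sens <- sum(pred == "TP" & truth == "TP") / sum(truth == "TP")
  spec <- sum(pred == "FP" & truth == "FP") / sum(truth == "FP")
  100 * (sens + spec) / 2
}

#' Evaluate a model's balanced accuracy on labeled events
#'
#' @param model a [train_random_forest()] model.
#' @param events labeled detection events with TP/FP labels.
#' @return balanced accuracy in percent.
#' @export
evaluate_balanced_accuracy <- function(model, events) {
  tab <- feature_table(events)
  balanced_accuracy(tab$y, predict_classes(model, tab$X))
}

#' Train many forests and keep the representative one
#'
#' Trains `n_forests` forests, each on a balanced training set drawn with a
#' fresh FP sample (seeds derived from `rng_seed`), evaluates each on the
#' evaluation events, and returns the forest whose balanced accuracy lies
#' closest to the mean over all forests (ties resolve to the lower seed
#' index), together with the accuracy distribution.
#'
#' @param train_events labeled events of the training period.
#' @param eval_events labeled events of the evaluation period.
#' @param plan a [sampling_plan()]; its seed field is replaced per forest.
#' @param n_forests number of forests (default 100).
#' @param n_trees trees per forest.
#' @param rng_seed master seed.
#' @return list with `model`, `accuracies` (length `n_forests`),
#'   `mean_accuracy`, `chosen` (index).
#' @export
select_representative_forest <- function(train_events, eval_events,
                                         plan = sampling_plan(),
                                         n_forests = 100, n_trees = 1000,
                                         rng_seed = 1) {
  models <- vector("list", n_forests)
  acc <- numeric(n_forests)
  for (i in seq_len(n_forests)) {
    plan_i <- plan
    plan_i$rng_seed <- derive_seed(rng_seed, i)
    tab <- build_balanced_training_set(train_events, plan_i)
    models[[i]] <- train_random_forest(tab, n_trees = n_trees,
                                       rng_seed = derive_seed(rng_seed, 10000L + i))
    acc[i] <- evaluate_balanced_accuracy(models[[i]], eval_events)
  }
  chosen <- which.min(abs(acc - mean(acc)))[1L]
  list(model = models[[chosen]], accuracies = acc,
       mean_accuracy = mean(acc), chosen = chosen)
}

#' Filter alarms with a trained forest
#'
#' Events the model classifies as FP are suppressed; the survivors are the
#' system's final alarms. When ground-truth TP/FP labels are present, the
#' confusion matrix and the percentage reduction of false alarms
#' (`100 * fp_as_fp / (fp_as_fp + fp_as_tp)`) are also returned.
#'
#' @param model a [train_random_forest()] model (or a function, see
#'   [predict_classes()]).
#' @param events detection events with the model's feature columns.
#' @return list with `events` (surviving alarms), `predictions`,
#'   `confusion` (a [confusion_matrix()] or NULL), `fp_reduction_pct`
#'   (or NA).
#' @export
classify_events <- function(model, events) {
  stopifnot(is.data.frame(events))
  fcols <- grep("^W_", names(events), value = TRUE)
  X <- as.matrix(events[, fcols, drop = FALSE])
  pred <- predict_classes(model, X)
  kept <- events[pred == "TP", , drop = FALSE]
  cm <- NULL; red <- NA_real_
  if (any(events$label %in% c("TP", "FP"))) {
    lab <- events$label
    cm <- confusion_matrix(
      tp_as_tp = sum(lab == "TP" & pred == "TP"),
      tp_as_fp = sum(lab == "TP" & pred == "FP"),
      fp_as_fp = sum(lab == "FP" & pred == "FP"),
      fp_as_tp = sum(lab == "FP" & pred == "TP"))
    if (cm$fp_as_fp + cm$fp_as_tp > 0)
      red <- 100 * cm$fp_as_fp / (cm$fp_as_fp + cm$fp_as_tp)
  }
  list(events = kept, predictions = pred, confusion = cm,
       fp_reduction_pct = red)
}

#' Balanced accuracy as a function of forest size
#'
#' Trains one forest per requested size on the same training table and
#' seed and evaluates each on the evaluation events.
#'
#' @param table a [feature_table()].
#' @param sizes vector of tree counts (>= 1).
#' @param eval_events labeled evaluation events.
#' @param rng_seed integer seed (shared across sizes).
#' @return data.frame with columns `size`, `balanced_accuracy_pct`, in size
#'   order.
#' @export
forest_size_curve <- function(table, sizes, eval_events, rng_seed = 1) {
  if (any(sizes < 1)) stop("forest sizes must be >= 1")
  sizes <- sort(as.integer(sizes))
  acc <- vapply(sizes, function(s) {
    m <- train_random_forest(table, n_trees = s, rng_seed = rng_seed)
    evaluate_balanced_accuracy(m, eval_events)
  }, 0)
  data.frame(size = sizes, balanced_accuracy_pct = acc)
}
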
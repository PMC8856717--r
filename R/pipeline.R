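#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with the
#' blocks `seed`, `output_dir`, `synthetic` (or `input` files), `detector`,
#' `classifier` and `surrogate`. Missing required fields raise an error
#' naming the field.
#'
#' @param config file path to a YAML config, or a named list.
#' @return validated config list of class `RunConfig`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  required <- c("seed", "output_dir", "synthetic", "detector",
                "classifier", "surrogate")
  for (f in required)
    if (is.null(config[[f]])) stop("config field missing: ", f)
  for (f in c("combination"))
    if (is.null(config$detector[[f]])) stop("config field missing: detector.", f)
  structure(config, class = c("RunConfig", "list"))
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647))
}

build_spec_from_config <- function(sc) {
  preset <- if (is.null(sc$preset)) "gaers" else tolower(sc$preset)
  fields <- setdiff(names(sc), c("preset", "sites", "roles"))
  args <- sc[fields]
  if (!is.null(sc$sites))
    args$channels <- synthetic_channels(unlist(sc$sites),
                                        roles = if (is.null(sc$roles)) NULL
                                                else unlist(sc$roles))
  for (nm in c("swd_freq_hz", "swd_duration_s", "precursor_lead_s",
               "precursor_freq_hz", "spindle_freq_hz", "sws_freq_hz",
               "spindle_duration_s"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.numeric(unlist(args[[nm]]))
  switch(preset,
         gaers = do.call(gaers_spec, args),
         wagrij = do.call(wagrij_spec, args),
         do.call(synthetic_spec, args))
}

#' Run the full prediction pipeline
#'
#' Executes, in order: synthetic-recording generation (or file input), band
#' energies, the threshold sweep for the configured site combination,
#' threshold calibration to the target sensitivity, detection and labeling
#' at the calibrated threshold, the chronological train/evaluation split,
#' training of the representative random forest, alarm filtering, and the
#' permutation surrogate test. All artifacts (sweep table, labeled events,
#' metrics, surrogate verdict) are written to the output directory, stamped
#' with the configuration hash and seed.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return the run report, invisibly (also written as `metrics.json`).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  seed <- config$seed
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(config), seed = seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- input -------------------------------------------------------------
  sim <- stage("simulate", {
    if (!is.null(config$input)) {
      rec <- read_recording(config$input$recording)
      ann <- read_annotation(config$input$annotation)
      list(record = rec, annotation = ann)
    } else {
      spec <- build_spec_from_config(config$synthetic)
      generate_recording(spec, rng_seed = derive_seed(seed, 101L))
    }
  })
  record <- sim$record; annotation <- sim$annotation

  dc <- config$detector
  sites <- unlist(dc$combination)
  stride_s <- if (is.null(dc$stride_s)) 0.01 else dc$stride_s
  refractory_s <- if (is.null(dc$refractory_s)) 1.0 else dc$refractory_s

  energies <- stage("spectral",
    band_energy_series(record, stride_s = stride_s, channels = sites))

  sweep <- stage("sweep",
    sweep_thresholds(record, annotation, sites, energies = energies,
                     refractory_s = refractory_s))
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)

  target <- if (is.null(dc$target_sensitivity_pct)) 90 else
    dc$target_sensitivity_pct
  cal <- stage("calibrate",
    calibrate_threshold(record, annotation, sites,
                        target_sensitivity_pct = target,
                        energies = energies, refractory_s = refractory_s))

  labeled <- stage("detect", {
    prod <- channel_product(energies, sites)
    evs <- detect_events(prod, energies,
                         detector_config(threshold = cal$threshold,
                                         refractory_s = refractory_s))
    evs <- rescore_events(evs, prod, energies, annotation)
    label_detections(evs, annotation)
  })
  utils::write.csv(labeled$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)

  # --- classifier --------------------------------------------------------
  cc <- config$classifier
  frac <- if (is.null(cc$train_fraction)) 0.7 else cc$train_fraction
  n_trees <- if (is.null(cc$n_trees)) 1000 else cc$n_trees
  n_forests <- if (is.null(cc$n_forests)) 100 else cc$n_forests
  plan <- sampling_plan(mode = if (is.null(cc$mode)) "undersample" else cc$mode,
                        oversample_factor = if (is.null(cc$oversample_factor))
                          4 else cc$oversample_factor)
  spl <- split_events_chronological(labeled$events, record_duration(record),
                                    frac = frac,
                                    start_time = record$start_time)
  rf <- stage("train",
    select_representative_forest(spl$train, spl$eval, plan = plan,
                                 n_forests = n_forests, n_trees = n_trees,
                                 rng_seed = derive_seed(seed, 202L)))
  filt <- stage("classify", classify_events(rf$model, spl$eval))

  # prediction metrics on the evaluation period, before and after filtering
  cut <- record$start_time + frac * record_duration(record)
  eval_swds <- which(annotation$onset_s > cut)
  eval_hours <- (1 - frac) * record_duration(record) / 3600
  pred_of <- function(evts) {
    tp <- evts[evts$label == "TP" & !is.na(evts$swd_index), , drop = FALSE]
    length(intersect(unique(tp$swd_index), eval_swds))
  }
  before <- prediction_metrics(pred_of(spl$eval),
                               length(eval_swds) - pred_of(spl$eval),
                               sum(spl$eval$label == "FP"), eval_hours)
  after <- prediction_metrics(pred_of(filt$events),
                              length(eval_swds) - pred_of(filt$events),
                              sum(filt$events$label == "FP"), eval_hours)

  sur_cfg <- config$surrogate
  sur <- stage("surrogate", {
    tab <- build_balanced_training_set(spl$train, {
      p <- plan; p$rng_seed <- derive_seed(seed, 303L); p
    })
    permutation_null_test(tab, spl$eval,
                          n_randomizations = if (is.null(sur_cfg$n_randomizations))
                            200 else sur_cfg$n_randomizations,
                          rng_seed = derive_seed(seed, 404L),
                          n_trees = if (is.null(sur_cfg$n_trees)) n_trees
                                    else sur_cfg$n_trees)
  })
  utils::write.csv(data.frame(null_balanced_accuracy_pct = sur$null_values),
                   file.path(out_dir, "surrogate_null.csv"), row.names = FALSE)

  report <- list(
    stamp = stamp,
    n_swd = nrow(annotation),
    threshold = cal$threshold,
    calibration_sensitivity_pct = cal$achieved_sensitivity_pct,
    eval_before = before,
    eval_after = after,
    fp_reduction_pct = filt$fp_reduction_pct,
    confusion = if (is.null(filt$confusion)) NULL else unclass(filt$confusion),
    forest_mean_balanced_accuracy_pct = rf$mean_accuracy,
    surrogate = list(
      observed_balanced_accuracy_pct = sur$observed_balanced_accuracy_pct,
      q95 = sur$q95, p_value = sur$p_value, significant = sur$significant))
  jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
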
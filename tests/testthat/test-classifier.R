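test_that("balanced training sets have the exact prescribed composition", {
  ev <- separable_events(100, 5000, seed = 1)
  under <- build_balanced_training_set(ev, sampling_plan("undersample",
                                                         rng_seed = 1))
  expect_equal(length(under$y), 200)
  expect_equal(as.vector(table(under$y)), c(100, 100))
  over <- build_balanced_training_set(
    ev, sampling_plan("oversample", oversample_factor = 4, rng_seed = 1))
  expect_equal(length(over$y), 800)
  expect_equal(as.vector(table(over$y)), c(400, 400))
  # oversampling replicates each TP row exactly `factor` times
  expect_equal(sum(duplicated(over$X[over$y == "TP", ])), 300)
  # FP draws are without replacement
  expect_false(any(duplicated(over$X[over$y == "FP", ])))
  ev_small <- separable_events(100, 150, seed = 2)
  expect_error(build_balanced_training_set(
    ev_small, sampling_plan("oversample", oversample_factor = 4)),
    "need 400")
  expect_error(build_balanced_training_set(separable_events(3, 100)),
               "at least 5")
  expect_error(sampling_plan("oversample", oversample_factor = 1),
               "at least 2")
})

test_that("the forest separates stated separable classes and is calibrated on noise", {
  train <- separable_events(500, 5000, mu_tp = 3, mu_fp = 1, sd = 0.5,
                            seed = 10)
  eval_ev <- separable_events(250, 250, mu_tp = 3, mu_fp = 1, sd = 0.5,
                              seed = 11)
  tab <- build_balanced_training_set(train, sampling_plan(rng_seed = 3))
  model <- train_random_forest(tab, n_trees = 200, rng_seed = 4)
  expect_gte(evaluate_balanced_accuracy(model, eval_ev), 95)
  # permuted training labels land at chance on held-out data; a single
  # permutation is amplified by majority voting, so the calibration property
  # is on the mean over permutations
  accs <- vapply(1:20, function(i) {
    perm <- tab
    set.seed(12 + i)
    perm$y <- sample(perm$y)
    evaluate_balanced_accuracy(
      train_random_forest(perm, n_trees = 200, rng_seed = 4), eval_ev)
  }, 0)
  expect_gte(mean(accs), 45)
  expect_lte(mean(accs), 55)
})

test_that("training and prediction are deterministic under a fixed seed", {
  train <- separable_events(50, 500, mu_tp = 1.5, mu_fp = 1, sd = 0.5,
                            seed = 20)
  eval_ev <- separable_events(50, 50, mu_tp = 1.5, mu_fp = 1, sd = 0.5,
                              seed = 21)
  tab <- build_balanced_training_set(train, sampling_plan(rng_seed = 5))
  m1 <- train_random_forest(tab, n_trees = 51, rng_seed = 6)
  m2 <- train_random_forest(tab, n_trees = 51, rng_seed = 6)
  X <- feature_table(eval_ev)$X
  expect_identical(predict_classes(m1, X), predict_classes(m2, X))
  expect_error(train_random_forest(
    structure(list(X = tab$X[tab$y == "TP", ], y = droplevels(tab$y[tab$y == "TP"]),
                   t = tab$t[tab$y == "TP"]), class = "FeatureTable")),
    "both classes")
})

test_that("the chronological split never leaks evaluation events into training", {
  ev <- separable_events(50, 200, seed = 30)
  ev$t <- runif(250, 0, 1000)
  spl <- split_events_chronological(ev, duration_s = 1000, frac = 0.7)
  expect_lte(max(spl$train$t), 700)
  expect_gt(min(spl$eval$t), 700)
  expect_equal(nrow(spl$train) + nrow(spl$eval), nrow(ev))
})

test_that("the representative forest sits closest to the ensemble mean", {
  train <- separable_events(40, 400, mu_tp = 2, mu_fp = 1, sd = 0.8, seed = 40)
  eval_ev <- separable_events(40, 60, mu_tp = 2, mu_fp = 1, sd = 0.8, seed = 41)
  sel <- select_representative_forest(train, eval_ev,
                                      plan = sampling_plan("undersample"),
                                      n_forests = 5, n_trees = 50,
                                      rng_seed = 7)
  expect_length(sel$accuracies, 5)
  expect_equal(abs(sel$accuracies[sel$chosen] - sel$mean_accuracy),
               min(abs(sel$accuracies - sel$mean_accuracy)))
  expect_lte(abs(sel$accuracies[sel$chosen] - sel$mean_accuracy),
             stats::sd(sel$accuracies) + 1e-12)
})

test_that("alarm filtering follows the model and reports the FP reduction", {
  ev <- separable_events(20, 80, seed = 50)
  keep_all <- classify_events(function(X) rep("TP", nrow(X)), ev)
  expect_equal(nrow(keep_all$events), nrow(ev))
  expect_equal(keep_all$fp_reduction_pct, 0)
  drop_all <- classify_events(function(X) rep("FP", nrow(X)), ev)
  expect_equal(nrow(drop_all$events), 0)
  expect_equal(drop_all$fp_reduction_pct, 100)
  # filtering can only remove alarms
  train <- separable_events(100, 1000, mu_tp = 2, mu_fp = 1, seed = 51)
  tab <- build_balanced_training_set(train, sampling_plan(rng_seed = 8))
  model <- train_random_forest(tab, n_trees = 100, rng_seed = 9)
  res <- classify_events(model, ev)
  expect_lte(sum(res$events$label == "TP"), sum(ev$label == "TP"))
  expect_equal(res$confusion$tp_as_tp + res$confusion$tp_as_fp,
               sum(ev$label == "TP"))
})

test_that("accuracy grows (or holds) with forest size on separable data", {
  # deterministic, widely separated classes: perfect at any size
  train0 <- separable_events(50, 50, mu_tp = 5, mu_fp = 1, sd = 0.1, seed = 60)
  eval0 <- separable_events(50, 50, mu_tp = 5, mu_fp = 1, sd = 0.1, seed = 61)
  tab0 <- feature_table(train0)
  curve0 <- forest_size_curve(tab0, c(1, 9, 33), eval0, rng_seed = 10)
  expect_equal(curve0$balanced_accuracy_pct, rep(100, 3))
  curve1 <- forest_size_curve(tab0, 1, eval0, rng_seed = 10)
  expect_equal(nrow(curve1), 1)
  # noisy separable data: a large forest is at least as good as one tree
  wins <- 0
  for (s in 1:25) {
    tr <- separable_events(60, 60, mu_tp = 2, mu_fp = 1, sd = 1, seed = 100 + s)
    te <- separable_events(60, 60, mu_tp = 2, mu_fp = 1, sd = 1, seed = 200 + s)
    cv <- forest_size_curve(feature_table(tr), c(1, 101), te, rng_seed = s)
    if (cv$balanced_accuracy_pct[2] >= cv$balanced_accuracy_pct[1] - 2)
      wins <- wins + 1
  }
  expect_gte(wins, 23)
})
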
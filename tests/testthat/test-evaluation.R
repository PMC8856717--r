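test_that("prediction sensitivity reproduces the printed conversions", {
  expect_equal(round(prediction_metrics(200, 209, 0, 24)$sensitivity_pct), 49)
  expect_equal(round(prediction_metrics(349, 171, 0, 24)$sensitivity_pct), 67)
  expect_equal(round(prediction_metrics(368, 41, 0, 24)$sensitivity_pct), 90)
  expect_equal(prediction_metrics(0, 10, 5, 2)$sensitivity_pct, 0)
  expect_equal(prediction_metrics(10, 0, 5, 2)$sensitivity_pct, 100)
  expect_equal(prediction_metrics(10, 0, 6, 2)$fp_per_h, 3)
  expect_error(prediction_metrics(0, 0, 1, 1), "undefined")
  expect_error(prediction_metrics(1, 1, 1, 0), "positive")
})

test_that("prediction metrics are scale-free in the counts", {
  a <- prediction_metrics(30, 20, 40, 4)
  b <- prediction_metrics(60, 40, 80, 8)
  expect_equal(a$sensitivity_pct, b$sensitivity_pct)
  expect_equal(a$fp_per_h, b$fp_per_h)
})

test_that("classification metrics follow their defining formulas", {
  perfect <- classification_metrics(confusion_matrix(37, 0, 81, 0))
  expect_equal(perfect$balanced_accuracy_pct, 100)
  expect_equal(perfect$f1_pct, 100)
  # classifying everything TP on balanced classes gives 50%
  all_tp <- classification_metrics(confusion_matrix(50, 0, 0, 50))
  expect_equal(all_tp$balanced_accuracy_pct, 50)
  m <- classification_metrics(confusion_matrix(49, 51, 52, 48))
  expect_equal(m$sensitivity_pct, 49)
  expect_equal(m$specificity_pct, 52)
  expect_equal(m$balanced_accuracy_pct, 50.5)
  expect_equal(m$precision_pct, 100 * 49 / 97)
  # F1 is zero when nothing is ever called TP
  none <- classification_metrics(confusion_matrix(0, 10, 10, 0))
  expect_equal(none$f1_pct, 0)
  expect_error(classification_metrics(confusion_matrix(0, 0, 3, 2)), "present")
})

test_that("group summaries average thresholds within combination first", {
  sw <- data.frame(
    combination = rep(c("a/b/c", "d/e/f", "g/h"), each = 2),
    group = rep(c("CCC", "CCC", "CC"), each = 2),
    sensitivity_pct = c(80, 60, 40, 20, 50, 30),
    fp_per_h = c(1, 3, 5, 7, 9, 11))
  g <- group_combinations(sw)
  ccc <- g[g$group == "CCC", ]
  expect_equal(ccc$n_combinations, 2)
  expect_equal(ccc$mean_sensitivity_pct, mean(c(70, 30)))
  expect_equal(ccc$sem_sensitivity_pct, stats::sd(c(70, 30)) / sqrt(2))
  # single-combination group mean equals that combination's mean
  cc <- g[g$group == "CC", ]
  expect_equal(cc$mean_sensitivity_pct, 40)
  expect_true(is.na(cc$sem_sensitivity_pct))
  # empty groups are simply absent
  expect_setequal(g$group, c("CCC", "CC"))
  sw_bad <- sw; sw_bad$group[1] <- "XYZ"
  expect_error(group_combinations(sw_bad), "unknown group")
})

test_that("sensitivity/false-alarm correlation behaves like Pearson's r", {
  sw <- data.frame(combination = letters[1:5], group = "CCC",
                   sensitivity_pct = c(90, 70, 50, 30, 10),
                   fp_per_h = c(1, 2, 3, 4, 5))
  r <- sens_fp_correlation(sw)
  expect_equal(r$r, -1)
  expect_lt(r$p_value, 0.001)
  dup <- data.frame(combination = letters[1:4], group = "CCC",
                    sensitivity_pct = 50, fp_per_h = 1:4)
  expect_error(sens_fp_correlation(dup), "zero variance")
  expect_error(sens_fp_correlation(sw[1:2, ]), "at least 3")
})

test_that("permuted pairings of many combinations decorrelate", {
  set.seed(31)
  n <- 200
  sens <- sort(runif(n, 10, 90), decreasing = TRUE)
  fp <- sort(runif(n, 1, 200))
  ok <- 0
  for (p in 1:1000) {
    r <- stats::cor(sens, sample(fp))
    if (abs(r) < 0.2) ok <- ok + 1
  }
  expect_gte(ok / 1000, 0.95)
})

test_that("TP/FP energy summaries compare classes per band", {
  # identical feature distributions give identical class means
  ev <- separable_events(40, 60, mu_tp = 2, mu_fp = 2, sd = 0, seed = 1)
  s0 <- suppressWarnings(tp_fp_energy_summary(ev, n_fp_sample = 50))
  for (b in unique(s0$band)) {
    d <- s0[s0$band == b, ]
    expect_equal(d$mean_energy[d$class == "TP"],
                 d$mean_energy[d$class == "FP"])
  }
  # spindle-burst false positives separate in the spindle band
  set.seed(32)
  ev2 <- separable_events(40, 200, mu_tp = 3, mu_fp = 1, sd = 0.3, seed = 2)
  spind <- grep("^W_spindle", names(ev2), value = TRUE)
  ev2[ev2$label == "FP", spind] <- ev2[ev2$label == "FP", spind] + 3
  s2 <- tp_fp_energy_summary(ev2, n_fp_sample = 50, rng_seed = 4)
  d <- s2[s2$band == "spindle", ]
  expect_gt(d$mean_energy[d$class == "FP"], d$mean_energy[d$class == "TP"])
  expect_equal(d$n[d$class == "FP"], 50)
  # the FP sample is reproducible under a fixed seed
  s3 <- tp_fp_energy_summary(ev2, n_fp_sample = 50, rng_seed = 4)
  expect_identical(s2, s3)
  s4 <- tp_fp_energy_summary(ev2, n_fp_sample = 50, rng_seed = 5)
  expect_false(identical(s2$mean_energy, s4$mean_energy))
  # too few FPs: all are used, with a warning
  expect_warning(tp_fp_energy_summary(ev2[c(1:40, 41:60), ],
                                      n_fp_sample = 50), "fewer")
})
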
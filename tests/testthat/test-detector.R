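test_that("site-combination enumeration matches the canonical counts", {
  combos <- enumerate_site_combinations()
  expect_equal(sum(combos$n_sites == 3), 57)
  expect_equal(sum(combos$n_sites == 2), 28)
  expect_equal(nrow(combos), 85)
  # M2 sites only appear as the complete M2 triple
  m2 <- combos[grepl("M2", combos$combination), ]
  expect_equal(nrow(m2), 1)
  expect_equal(m2$group, "MCCC")
  expect_error(enumerate_site_combinations(c("S1_L4", "S1_L4")), "duplicate")
})

test_that("combination groups follow the anatomical membership rules", {
  cc <- enumerate_site_combinations(c("S1_L4", "S1_L5"))
  expect_equal(nrow(cc), 1)
  expect_equal(cc$group, "CC")
  ctt <- enumerate_site_combinations(c("S1_L6", "VPM", "rRTN"))
  expect_equal(ctt$group[ctt$n_sites == 3], "CTT")
  expect_equal(swdpredict:::combination_group(c("S1_L4", "S1_L5", "VPM")), "CCT")
  expect_equal(swdpredict:::combination_group(c("M2_5a", "M2_5b", "M2_6")), "MCCC")
})

test_that("the three criteria gate detections as specified", {
  times <- seq(0.5, 60, by = 0.1)
  n <- length(times)
  # no precursor energy -> no events
  en0 <- fake_energies(times, precursor = rep(0, n), sws = rep(1, n),
                       spindle = rep(1, n))
  ev0 <- detect_events(channel_product(en0, 1:3), en0,
                       detector_config(threshold = 0.1))
  expect_equal(nrow(ev0), 0)
  # super-threshold precursor vetoed by a larger slow-wave product
  prec <- rep(2, n)
  en1 <- fake_energies(times, precursor = prec, sws = 3 * prec,
                       spindle = rep(0.1, n))
  ev1 <- detect_events(channel_product(en1, 1:3), en1,
                       detector_config(threshold = 4))  # 2^3 = 8 > 4
  expect_equal(nrow(ev1), 0)
  # and by a larger spindle product
  en2 <- fake_energies(times, precursor = prec, sws = rep(0.1, n),
                       spindle = 3 * prec)
  expect_equal(nrow(detect_events(channel_product(en2, 1:3), en2,
                                  detector_config(threshold = 4))), 0)
})

test_that("super-threshold runs merge within the refractory window", {
  times <- seq(0.5, 30, by = 0.1)
  n <- length(times)
  prec <- rep(0.1, n)
  prec[times >= 5 & times <= 5.5] <- 2      # run 1
  prec[times >= 6.0 & times <= 6.4] <- 2    # run 2, gap 0.5 s < 1 s
  prec[times >= 10 & times <= 10.3] <- 3    # run 3, far away
  en <- fake_energies(times, precursor = prec, sws = rep(0.05, n),
                      spindle = rep(0.05, n))
  ev <- detect_events(channel_product(en, 1:3), en,
                      detector_config(threshold = 1, refractory_s = 1))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$t, c(5, 10))
  expect_equal(ev$peak, c(8, 27))
  # with no merging the runs stay separate
  ev_nm <- detect_events(channel_product(en, 1:3), en,
                         detector_config(threshold = 1, refractory_s = 0))
  expect_equal(nrow(ev_nm), 3)
  # event features are the per-channel, per-band energies at the run start
  expect_equal(unname(unlist(ev[1, grep("^W_precursor", names(ev))])),
               rep(2, 3))
  expect_length(attr(ev, "feature_names"), 9)
})

test_that("criteria 2 and 3 are scale-free", {
  times <- seq(0.5, 60, by = 0.1)
  set.seed(5)
  n <- length(times)
  en <- fake_energies(times, precursor = rexp(n), sws = rexp(n),
                      spindle = rexp(n))
  en_scaled <- en
  en_scaled$values <- en$values * 7
  tiny <- 1e-12
  ev1 <- detect_events(channel_product(en, 1:3), en,
                       detector_config(threshold = tiny))
  ev2 <- detect_events(channel_product(en_scaled, 1:3), en_scaled,
                       detector_config(threshold = tiny))
  expect_equal(ev1$t, ev2$t)
})

test_that("default threshold grids have the canonical sizes and ranges", {
  g3 <- default_threshold_grid(3)
  g2 <- default_threshold_grid(2)
  expect_length(g3, 14)
  expect_length(g2, 16)
  expect_equal(range(g3), c(0.1, 0.75))
  expect_equal(range(g2), c(0.005, 0.04))
  expect_equal(diff(g3), rep(diff(g3)[1], 13))  # linear spacing
  expect_error(default_threshold_grid(4), "2 or 3")
})

test_that("sweeps produce one row per threshold with monotone metrics", {
  spec <- gaers_spec(fs = 100, duration_s = 600, base_swd_rate_per_h = 40,
                     swd_duration_s = c(8, 12), diurnal_mod_amp = 0)
  sim <- generate_recording(spec, rng_seed = 3)
  en <- band_energy_series(sim$record, stride_s = 0.02)
  sw3 <- sweep_thresholds(sim$record, sim$annotation,
                          c("S1_L4", "S1_L5", "S1_L6"), energies = en)
  expect_equal(nrow(sw3), 14)
  expect_true(all(diff(sw3$sensitivity_pct) <= 1e-9))
  expect_true(all(diff(sw3$n_fp) <= 0))
  expect_true(all(sw3$sensitivity_pct >= 0 & sw3$sensitivity_pct <= 100))
  sw2 <- sweep_thresholds(sim$record, sim$annotation,
                          c("S1_L4", "S1_L5"), energies = en)
  expect_equal(nrow(sw2), 16)
  expect_true(all(diff(sw2$n_fp) <= 0))
  expect_error(sweep_thresholds(sim$record, sim$annotation,
                                c("S1_L4", "S1_L5", "S1_L6"), grid = -1),
               "positive")
})

test_that("threshold calibration reaches attainable targets monotonically", {
  spec <- gaers_spec(fs = 100, duration_s = 1200, base_swd_rate_per_h = 40,
                     swd_duration_s = c(8, 12), diurnal_mod_amp = 0,
                     channels = synthetic_channels(
                       c("S1_L4", "S1_L5", "S1_L6", "VPM", "Po", "rRTN")))
  sim <- generate_recording(spec, rng_seed = 5)
  expect_gte(nrow(sim$annotation), 5)
  en <- band_energy_series(sim$record, stride_s = 0.02)
  combo <- c("S1_L4", "S1_L5", "S1_L6")
  c60 <- calibrate_threshold(sim$record, sim$annotation, combo,
                             target_sensitivity_pct = 60, energies = en)
  expect_gte(c60$achieved_sensitivity_pct, 60)
  c30 <- calibrate_threshold(sim$record, sim$annotation, combo,
                             target_sensitivity_pct = 30, energies = en)
  expect_gte(c30$threshold, c60$threshold)
  # an unreachable target falls back to the floor with a flag: thalamic
  # channels carry no precursor, so full sensitivity is not attainable there
  en_t <- band_energy_series(sim$record, stride_s = 0.02,
                             channels = c("VPM", "Po", "rRTN"))
  expect_warning(
    c100 <- calibrate_threshold(sim$record, sim$annotation,
                                c("VPM", "Po", "rRTN"),
                                target_sensitivity_pct = 100,
                                energies = en_t),
    "unreachable")
  expect_true(c100$flagged)
  expect_equal(c100$threshold, 0.1)
  # too few SWDs is a precondition error
  expect_error(calibrate_threshold(sim$record, seizure_annotation(), combo),
               "at least 5")
})
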
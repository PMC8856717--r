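test_that("the wavelet ridge sits at the tone frequency and scales with power", {
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  rec <- tiny_record(sin(2 * pi * 7 * t), fs = fs)
  sp <- wavelet_spectrum(rec, 1, freqs = seq(3, 15, by = 0.5))
  expect_equal(as.numeric(rownames(sp))[which.max(rowMeans(sp))], 7)

  rec2 <- tiny_record(3 * sin(2 * pi * 7 * t), fs = fs)
  sp2 <- wavelet_spectrum(rec2, 1, freqs = seq(3, 15, by = 0.5))
  expect_equal(sp2, 9 * sp, tolerance = 1e-8)

  expect_true(all(wavelet_spectrum(tiny_record(numeric(200)), 1, 5) == 0))
  expect_error(wavelet_spectrum(rec, 1, numeric(0)), "non-empty")
  expect_error(wavelet_spectrum(rec, 1, 60), "fs/2")
})

test_that("equal-amplitude tones carry equal band-integrated power", {
  # a sharp wavelet (morlet_param 20) resolves 2-Hz-wide bands; the FFT
  # periodogram is the independent reference for both band powers
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  x <- sin(2 * pi * 4 * t) + sin(2 * pi * 15 * t)
  rec <- tiny_record(x, fs = fs)
  sp <- wavelet_spectrum(rec, 1, freqs = seq(1, 30, by = 0.25),
                         morlet_param = 20)
  f <- as.numeric(rownames(sp))
  pw <- rowMeans(sp)
  low <- sum(pw[f >= 3 & f <= 5]) * 0.25
  high <- sum(pw[f >= 14 & f <= 16]) * 0.25
  expect_equal(low / high, 1, tolerance = 0.2)
  oracle_low <- periodogram_band_power(x, fs, 3, 5)
  oracle_high <- periodogram_band_power(x, fs, 14, 16)
  expect_equal(oracle_low / oracle_high, 1, tolerance = 1e-6)
  expect_equal(low / oracle_low, 1, tolerance = 0.2)
})

test_that("median normalization gives unit medians on stationary noise", {
  set.seed(1)
  rec <- tiny_record(rnorm(120 * 100), fs = 100)
  en <- band_energy_series(rec, normalization = "median")
  meds <- apply(en$values[, 1, ], 1, stats::median)
  expect_true(all(abs(meds - 1) < 0.05))
  # scaled_median is the same series divided by the scale factor
  en_s <- band_energy_series(rec, normalization = "scaled_median",
                             norm_scale = 2.5)
  expect_equal(en_s$values, en$values / 2.5, tolerance = 1e-10)
})

test_that("a zero signal has no usable normalization reference", {
  expect_error(band_energy_series(tiny_record(numeric(2000))),
               "degenerate")
  expect_error(band_energy_series(tiny_record(rnorm(10), fs = 100)),
               "shorter than")
})

test_that("an embedded tone lifts its band well above baseline", {
  fs <- 100
  set.seed(3)
  x <- rnorm(20 * fs)
  t <- (0:(20 * fs - 1)) / fs
  x[t >= 10 & t < 12] <- x[t >= 10 & t < 12] + 2 * sin(2 * pi * 7 * t[t >= 10 & t < 12])
  en <- band_energy_series(tiny_record(x, fs = fs), normalization = "median")
  w_in <- en$values["precursor", 1, which.min(abs(en$times - 11.5))]
  w_out <- en$values["precursor", 1, which.min(abs(en$times - 5))]
  expect_gt(w_in, 3 * w_out)
})

test_that("band energies are stride-invariant at shared time stamps", {
  set.seed(2)
  rec <- tiny_record(rnorm(30 * 100), fs = 100)
  full <- band_energy_series(rec, normalization = "median")
  coarse <- band_energy_series(rec, normalization = "median", stride_s = 0.1)
  shared <- match(coarse$times, full$times)
  expect_false(anyNA(shared))
  expect_equal(coarse$values[, 1, ], full$values[, 1, shared])
})

test_that("channel products follow the algebra of the factors", {
  set.seed(4)
  rec <- signal_record(matrix(rnorm(3 * 60 * 100), 3), fs = 100,
                       channel_sites = c("S1_L4", "S1_L5", "S1_L6"))
  en <- band_energy_series(rec, normalization = "median")
  pr <- channel_product(en, 1:3)
  expect_true(all(pr$P >= 0))
  # medians of products of independent channels stay near median(W)^3
  expect_true(all(abs(apply(pr$P, 1, stats::median) - 1) < 0.25))
  # duplicated pair is the square
  pr2 <- channel_product(en, c(1, 1))
  expect_equal(pr2$P["precursor", ], en$values["precursor", 1, ]^2)
  # a zero factor annihilates the product
  en0 <- en
  en0$values["precursor", 2, 100] <- 0
  expect_equal(unname(channel_product(en0, 1:3)$P["precursor", 100]), 0)
  expect_error(channel_product(en, 1), "2 or 3")
  expect_error(channel_product(en, c(1, 2, 3, 3)), "2 or 3")
})

test_that("wavelet band energy agrees with a Welch periodogram oracle", {
  fs <- 100
  set.seed(11)
  # band-limited stationary noise: white noise bandpassed to 4-12 Hz
  x <- signal::filtfilt(signal::butter(4, c(4, 12) / (fs / 2), "pass"),
                        rnorm(110 * fs))
  rec <- tiny_record(x, fs = fs)
  band <- colMeans(wavelet_spectrum(rec, 1, freqs = seq(5, 10, by = 0.5)))
  tt <- record_times(rec)
  win_s <- 2
  starts <- seq(5, 105 - win_s, length.out = 50)
  mine <- oracle <- numeric(50)
  for (k in seq_along(starts)) {
    mine[k] <- mean(band[tt > starts[k] & tt <= starts[k] + win_s])
    idx <- (round(starts[k] * fs) + 1L):round((starts[k] + win_s) * fs)
    oracle[k] <- periodogram_band_power(x[idx], fs, 5, 10)
  }
  expect_gt(stats::cor(mine, oracle, method = "spearman"), 0.9)
})
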
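# Shared fixtures: small records and hand-built series used across tests.

tiny_record <- function(x, fs = 100, sites = "S1_L4") {
  signal_record(if (is.matrix(x)) x else matrix(x, nrow = 1L),
                fs = fs, channel_sites = sites)
}

# A hand-built BandEnergySeries with one channel per site and given
# per-band values (each a vector over time).
fake_energies <- function(times, precursor, sws, spindle,
                          sites = c("S1_L4", "S1_L5", "S1_L6")) {
  nb <- 3L; nc <- length(sites); nt <- length(times)
  vals <- array(0, dim = c(nb, nc, nt),
                dimnames = list(c("precursor", "sws", "spindle"), sites, NULL))
  for (c_i in seq_len(nc)) {
    vals["precursor", c_i, ] <- precursor
    vals["sws", c_i, ] <- sws
    vals["spindle", c_i, ] <- spindle
  }
  structure(list(times = times, values = vals, window_s = 0.5,
                 stride_s = diff(times[1:2]), normalization = "none",
                 norm_ref = matrix(1, nb, nc), bands = band_defs(),
                 channel_sites = sites, fs = 1 / diff(times[1:2])),
            class = "BandEnergySeries")
}

# Labeled event table with gaussian features for classifier tests:
# TP events have precursor-band features ~N(mu_tp, sd^2), FP ~N(mu_fp, sd^2);
# the other bands are N(1, sd^2) noise for both classes.
separable_events <- function(n_tp, n_fp, mu_tp = 3, mu_fp = 1, sd = 0.5,
                             seed = 1, sites = c("S1_L4", "S1_L5", "S1_L6")) {
  set.seed(seed)
  n <- n_tp + n_fp
  lab <- c(rep("TP", n_tp), rep("FP", n_fp))
  df <- data.frame(t = seq_len(n), label = lab)
  for (s in sites) {
    mu <- ifelse(lab == "TP", mu_tp, mu_fp)
    df[[paste0("W_precursor_", s)]] <- pmax(0, stats::rnorm(n, mu, sd))
    df[[paste0("W_sws_", s)]] <- pmax(0, stats::rnorm(n, 1, sd))
    df[[paste0("W_spindle_", s)]] <- pmax(0, stats::rnorm(n, 1, sd))
  }
  df
}

# Events whose features carry no class signal at all (exchangeable labels).
exchangeable_events <- function(n_tp, n_fp, seed = 1,
                                sites = c("S1_L4", "S1_L5", "S1_L6")) {
  separable_events(n_tp, n_fp, mu_tp = 1, mu_fp = 1, sd = 0.5, seed = seed,
                   sites = sites)
}

# Welch-style band power oracle: mean periodogram power of `x` within
# [f_lo, f_hi], independent of the wavelet code path.
periodogram_band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / n * fs
  keep <- f >= f_lo & f <= f_hi
  sum(2 * Mod(X[keep])^2 / n^2)
}
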
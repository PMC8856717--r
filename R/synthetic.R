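#' Default channel layout for a synthetic recording
#'
#' Builds the per-channel table used by [synthetic_spec()]. Each channel has
#' a recording site, a precursor role, a spike amplitude and a spike
#' polarity. Defaults encode the stylised electrophysiology of the two
#' absence models: cortical S1 spikes of ~700 uV positive polarity, thalamic
#' spikes smaller (~500 uV) and of reversed polarity, and precursor
#' oscillations confined to the deep S1 channels (`precursor_strong`);
#' thalamic and M2 channels carry no precursor of their own
#' (`precursor_none`).
#'
#' @param sites character vector of site labels (see [swd_sites()]).
#' @param roles optional character vector of roles
#'   (`precursor_strong`, `precursor_weak`, `precursor_none`); default by
#'   site class (S1 strong, others none).
#' @return data.frame with columns `site`, `role`, `spike_amp_uv`,
#'   `polarity`.
#' @export
synthetic_channels <- function(sites = c("S1_L4", "S1_L5", "S1_L6"),
                               roles = NULL) {
  cls <- site_class(sites)
  if (anyNA(cls)) stop("sites must be from the controlled vocabulary")
  if (is.null(roles))
    roles <- ifelse(cls == "C", "precursor_strong", "precursor_none")
  stopifnot(length(roles) == length(sites),
            all(roles %in% c("precursor_strong", "precursor_weak", "precursor_none")))
  data.frame(site = sites, role = roles,
             spike_amp_uv = ifelse(cls == "T", 500, 700),
             polarity = ifelse(cls == "T", -1, 1),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic annotated LFP recording
#'
#' Collects every tunable of the generator. The defaults emulate a GAERS-like
#' recording: SWDs at 5-7 Hz lasting 10-30 s at an average rate of 17 per
#' hour with a sinusoidal 24-h rate modulation, each preceded by a 5-9 Hz
#' precursor oscillation starting 0.3-0.9 s before onset in the
#' `precursor_strong` channels, on a 1/f Gaussian background with sleep
#' spindle (7-20 Hz) and slow-wave-sleep (3-5 Hz) confounders. Use
#' [wagrij_spec()] for the WAG/Rij-like preset (8-10 Hz, ~7 s, 10 per hour,
#' no diurnal modulation).
#'
#' The background standard deviation default (135.9 uV) is chosen so that
#' twice the 99th percentile of the absolute Gaussian background equals the
#' 700 uV cortical spike amplitude, which makes the onset-marking rule (first
#' spike of twice the background amplitude) exactly satisfiable.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s recording duration in seconds.
#' @param channels channel table from [synthetic_channels()].
#' @param base_swd_rate_per_h mean SWD rate (events/hour).
#' @param diurnal_mod_amp relative amplitude in `[0, 1)` of the 24-h
#'   sinusoidal rate modulation.
#' @param diurnal_peak_h phase (hours) at which the rate peaks.
#' @param swd_freq_hz range of the SWD fundamental frequency.
#' @param swd_duration_s range of SWD durations (s).
#' @param background_sigma_uv background standard deviation (uV).
#' @param one_over_f_exponent exponent alpha of the 1/f^alpha background.
#' @param precursor_lead_s range of precursor lead times before onset (s),
#'   within (0, 5].
#' @param precursor_freq_hz range of precursor frequencies (Hz).
#' @param precursor_amp_sd named amplitudes of the precursor oscillation per
#'   role, in units of the background standard deviation.
#' @param spindle_rate_per_h sleep-spindle rate (events/hour).
#' @param spindle_freq_hz spindle frequency range (Hz).
#' @param spindle_duration_s spindle duration range (s).
#' @param sws_epochs_per_h slow-wave-sleep epochs per hour.
#' @param sws_epoch_duration_s duration of each SWS epoch (s).
#' @param sws_freq_hz SWS oscillation frequency range (Hz).
#' @param confounder_amp_sd amplitude of spindle/SWS oscillations (background
#'   SD units).
#' @param min_gap_s minimum inter-SWD gap (s).
#' @param strain_tag strain tag stored on the generated record.
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(fs = 500,
                           duration_s = 3600,
                           channels = synthetic_channels(),
                           base_swd_rate_per_h = 17,
                           diurnal_mod_amp = 0.5,
                           diurnal_peak_h = 12,
                           swd_freq_hz = c(5, 7),
                           swd_duration_s = c(10, 30),
                           background_sigma_uv = 135.9,
                           one_over_f_exponent = 1,
                           precursor_lead_s = c(0.3, 0.9),
                           precursor_freq_hz = c(5, 9),
                           precursor_amp_sd = c(precursor_strong = 1.0,
                                                precursor_weak = 0.3,
                                                precursor_none = 0),
                           spindle_rate_per_h = 30,
                           spindle_freq_hz = c(8, 16),
                           spindle_duration_s = c(0.5, 1),
                           sws_epochs_per_h = 4,
                           sws_epoch_duration_s = 30,
                           sws_freq_hz = c(3, 5),
                           confounder_amp_sd = 1,
                           min_gap_s = 5,
                           strain_tag = "SYNTHETIC") {
  spec <- list(fs = fs, duration_s = duration_s, channels = channels,
               base_swd_rate_per_h = base_swd_rate_per_h,
               diurnal_mod_amp = diurnal_mod_amp,
               diurnal_peak_h = diurnal_peak_h,
               swd_freq_hz = swd_freq_hz, swd_duration_s = swd_duration_s,
               background_sigma_uv = background_sigma_uv,
               one_over_f_exponent = one_over_f_exponent,
               precursor_lead_s = precursor_lead_s,
               precursor_freq_hz = precursor_freq_hz,
               precursor_amp_sd = precursor_amp_sd,
               spindle_rate_per_h = spindle_rate_per_h,
               spindle_freq_hz = spindle_freq_hz,
               spindle_duration_s = spindle_duration_s,
               sws_epochs_per_h = sws_epochs_per_h,
               sws_epoch_duration_s = sws_epoch_duration_s,
               sws_freq_hz = sws_freq_hz,
               confounder_amp_sd = confounder_amp_sd,
               min_gap_s = min_gap_s, strain_tag = strain_tag)
  validate_synthetic_spec(spec)
  structure(spec, class = "SyntheticSpec")
}

#' @rdname synthetic_spec
#' @param ... overrides passed on to [synthetic_spec()].
#' @export
gaers_spec <- function(...) {
  synthetic_spec(strain_tag = "GAERS", ...)
}

#' @rdname synthetic_spec
#' @export
wagrij_spec <- function(...) {
  args <- list(base_swd_rate_per_h = 10,
               diurnal_mod_amp = 0,
               swd_freq_hz = c(8, 10),
               swd_duration_s = c(5, 9),
               strain_tag = "WAGRij")
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_spec, args)
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (fs <= 0 || duration_s < 0) stop("fs and duration_s must be positive")
    if (base_swd_rate_per_h < 0 || spindle_rate_per_h < 0 || sws_epochs_per_h < 0)
      stop("rates must be non-negative")
    if (diurnal_mod_amp < 0 || diurnal_mod_amp >= 1)
      stop("diurnal modulation amplitude must be in [0, 1)")
    if (precursor_lead_s[1] <= 0 || precursor_lead_s[2] > 5)
      stop("precursor lead-time range must lie within (0, 5] s")
    if (!all(c("precursor_strong", "precursor_weak", "precursor_none") %in%
             names(precursor_amp_sd)))
      stop("precursor_amp_sd must name all three roles")
    if (nrow(channels) < 1L) stop("at least one channel required")
  })
  invisible(spec)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic integer hash used everywhere the package needs several
#' independent random streams from one user-facing seed (stages of the
#' pipeline, per-forest sampling seeds, permutation draws). Keeps derived
#' seeds within the 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stage stage index (integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 65536 * 30269 + as.numeric(stage) * 16807 +
                7919) %% 2147483629)
}

#' Sample SWD onset/offset times from an inhomogeneous Poisson process
#'
#' Event onsets follow a Poisson process with rate
#' `lambda(t) = base_rate * (1 + m * cos(2*pi*(t - peak)/24h))` (thinning),
#' reproducing the diurnal rate modulation of SWD occurrence. Durations are
#' drawn uniformly from `swd_duration_s`. Events are kept non-overlapping
#' with a minimum inter-event gap; a conflicting event's onset is re-drawn,
#' and after 1000 failed draws the remaining events are dropped.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer seed.
#' @return data.frame with columns `onset_s`, `offset_s` (possibly 0 rows).
#' @export
sample_seizure_times <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "SyntheticSpec"), spec$duration_s > 0)
  set.seed(rng_seed)
  rate_s <- spec$base_swd_rate_per_h / 3600
  m <- spec$diurnal_mod_amp
  lambda <- function(t)
    rate_s * (1 + m * cos(2 * pi * (t / 3600 - spec$diurnal_peak_h) / 24))
  lam_max <- rate_s * (1 + m)
  if (lam_max <= 0) return(seizure_annotation())
  n_cand <- stats::rpois(1L, lam_max * spec$duration_s)
  if (n_cand == 0L) return(seizure_annotation())
  cand <- sort(stats::runif(n_cand, 0, spec$duration_s))
  keep <- stats::runif(n_cand) < lambda(cand) / lam_max
  onsets <- cand[keep]
  if (length(onsets) == 0L) return(seizure_annotation())
  durs <- stats::runif(length(onsets), spec$swd_duration_s[1], spec$swd_duration_s[2])

  acc_on <- numeric(0); acc_off <- numeric(0)
  budget <- 1000L
  fits <- function(on, off) {
    off <= spec$duration_s && on >= 0 &&
      all(on >= acc_off + spec$min_gap_s | off <= acc_on - spec$min_gap_s)
  }
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- on + durs[i]
    while (!fits(on, off)) {
      if (budget <= 0L) return(seizure_annotation(acc_on, acc_off))
      budget <- budget - 1L
      repeat {
        on <- stats::runif(1L, 0, spec$duration_s)
        if (stats::runif(1L) < lambda(on) / lam_max) break
      }
      off <- on + durs[i]
    }
    acc_on <- c(acc_on, on); acc_off <- c(acc_off, off)
  }
  o <- order(acc_on)
  seizure_annotation(acc_on[o], acc_off[o])
}

# 1/f^alpha Gaussian noise with unit variance, via spectral shaping of white
# noise; frequencies below 0.5 Hz share the 0.5 Hz gain so the variance stays
# finite.
one_over_f_noise <- function(n, fs, alpha) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  if (alpha == 0) return(w[seq_len(n)])
  f <- c(0, seq_len(m - 1)) / m * fs
  f <- pmin(f, fs - f)            # two-sided frequency magnitude
  gain <- pmax(f, 0.5)^(-alpha / 2)
  gain[1L] <- 0                   # remove DC
  x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Raised-cosine-ramped tone burst, sampled on the record grid.
tone_burst <- function(t0, t1, freq, amp, fs, n, ramp_s = 0.05) {
  i0 <- max(1L, floor(t0 * fs) + 1L)
  i1 <- min(n, ceiling(t1 * fs))
  if (i1 < i0) return(NULL)
  tt <- ((i0:i1) - 1L) / fs
  env <- rep(1, length(tt))
  r <- ramp_s
  env <- pmin(1, pmax(0, (tt - t0) / r)) * pmin(1, pmax(0, (t1 - tt) / r))
  env <- (1 - cos(pi * pmin(1, env))) / 2
  list(idx = i0:i1, x = amp * env * sin(2 * pi * freq * (tt - t0)))
}

# One spike-wave cycle template on an absolute time grid: a narrow positive
# Gaussian spike followed by a slower half-sine wave of opposite sign.
swd_train <- function(onset, offset, freq, fs, n) {
  period <- 1 / freq
  n_cyc <- max(1L, floor((offset - onset) * freq))
  i0 <- max(1L, floor((onset - 0.1) * fs) + 1L)
  i1 <- min(n, ceiling((offset + 0.2) * fs))
  tt <- ((i0:i1) - 1L) / fs
  x <- numeric(length(tt))
  spike_sd <- 0.012
  for (k in seq_len(n_cyc) - 1L) {
    tk <- onset + k * period
    x <- x + exp(-(tt - tk)^2 / (2 * spike_sd^2))
    wl <- tk + 0.2 * period; wr <- tk + 0.9 * period
    in_w <- tt >= wl & tt <= wr
    x[in_w] <- x[in_w] - 0.45 * sin(pi * (tt[in_w] - wl) / (wr - wl))
  }
  list(idx = i0:i1, x = x)
}

#' Generate an annotated synthetic multichannel LFP recording
#'
#' Synthesises, per channel, a 1/f^alpha Gaussian background plus (i) SWD
#' spike-wave trains at the event times drawn by [sample_seizure_times()],
#' (ii) a precursor tone burst ending at each SWD onset, scaled by the
#' channel's precursor role, and (iii) spindle and slow-wave-sleep
#' oscillation bursts injected at interictal times. The cortical spike peak
#' equals twice the 99th percentile of the channel's absolute background
#' (the onset-marking convention); other channels scale with their
#' `spike_amp_uv` relative to the 700 uV cortical reference and carry their
#' configured polarity, with thalamic spike trains lagged by 4 ms. The
#' annotation stores the exact time of the first spike peak of each SWD.
#' Fully reproducible for a given seed.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer seed.
#' @return list with elements `record` (a [signal_record()]) and
#'   `annotation` (a [seizure_annotation()]).
#' @export
generate_recording <- function(spec, rng_seed) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  validate_synthetic_spec(spec)
  ann <- sample_seizure_times(spec, rng_seed)
  set.seed(derive_seed(rng_seed, 1L))
  n <- round(spec$duration_s * spec$fs)
  if (n < 1L) stop("duration too short for one sample")
  nch <- nrow(spec$channels)
  n_ev <- nrow(ann)

  # per-event draws (shared across channels)
  ev_freq <- stats::runif(n_ev, spec$swd_freq_hz[1], spec$swd_freq_hz[2])
  ev_lead <- stats::runif(n_ev, spec$precursor_lead_s[1], spec$precursor_lead_s[2])
  ev_pfreq <- stats::runif(n_ev, spec$precursor_freq_hz[1], spec$precursor_freq_hz[2])

  # snap onsets to the sample grid so the annotated first-spike peak is exact
  if (n_ev > 0L) {
    ann$onset_s <- round(ann$onset_s * spec$fs) / spec$fs
    ann$offset_s <- pmin(ann$offset_s, spec$duration_s)
  }

  hours <- spec$duration_s / 3600
  interictal_ok <- function(t0, t1) {
    n_ev == 0L ||
      all(t1 <= ann$onset_s - 1.5 | t0 >= ann$offset_s + 1)
  }
  draw_bursts <- function(count, dur_range, freq_range) {
    out <- list()
    tries <- 0L
    while (length(out) < count && tries < 50L * count + 50L) {
      tries <- tries + 1L
      d <- stats::runif(1L, dur_range[1], dur_range[2])
      t0 <- stats::runif(1L, 0, max(spec$duration_s - d, 0))
      if (interictal_ok(t0, t0 + d))
        out[[length(out) + 1L]] <- c(t0, t0 + d,
                                     stats::runif(1L, freq_range[1], freq_range[2]))
    }
    out
  }
  n_spindle <- stats::rpois(1L, spec$spindle_rate_per_h * hours)
  spindles <- draw_bursts(n_spindle, spec$spindle_duration_s, spec$spindle_freq_hz)
  n_sws <- stats::rpois(1L, spec$sws_epochs_per_h * hours)
  sws <- draw_bursts(n_sws, rep(spec$sws_epoch_duration_s, 2), spec$sws_freq_hz)

  sigma <- spec$background_sigma_uv
  # upward-only jitter keeps the first spike at or above twice the background
  amp_jit <- if (n_ev > 0L)
    matrix(stats::runif(n_ev * nch, 1.0, 1.15), n_ev, nch) else
    matrix(0, 0, nch)

  dat <- matrix(0, nrow = nch, ncol = n)
  for (c_i in seq_len(nch)) {
    ch <- spec$channels[c_i, ]
    bg <- sigma * one_over_f_noise(n, spec$fs, spec$one_over_f_exponent)
    p99 <- stats::quantile(abs(bg), 0.99, names = FALSE)
    x <- bg
    spike_amp <- (ch$spike_amp_uv / 700) * 2 * p99 * ch$polarity
    lag <- if (site_class(ch$site) %in% "T" && !is.na(site_class(ch$site))) 0.004 else 0
    for (e in seq_len(n_ev)) {
      tr <- swd_train(ann$onset_s[e] + lag, ann$offset_s[e] + lag,
                      ev_freq[e], spec$fs, n)
      x[tr$idx] <- x[tr$idx] + spike_amp * amp_jit[e, c_i] * tr$x
    }
    pre_amp <- spec$precursor_amp_sd[[ch$role]] * sigma
    if (pre_amp > 0) {
      for (e in seq_len(n_ev)) {
        tb <- tone_burst(ann$onset_s[e] - ev_lead[e], ann$onset_s[e],
                         ev_pfreq[e], pre_amp, spec$fs, n)
        if (!is.null(tb)) x[tb$idx] <- x[tb$idx] + tb$x
      }
    }
    conf_amp <- spec$confounder_amp_sd * sigma
    for (b in c(spindles, sws)) {
      tb <- tone_burst(b[1], b[2], b[3], conf_amp, spec$fs, n)
      if (!is.null(tb)) x[tb$idx] <- x[tb$idx] + tb$x
    }
    dat[c_i, ] <- x
  }
  record <- signal_record(dat, fs = spec$fs,
                          channel_sites = spec$channels$site,
                          strain_tag = spec$strain_tag)
  list(record = record, annotation = ann)
}
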
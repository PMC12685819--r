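# Synthetic stand-ins for the three data sources the framework consumes:
# a 62-feature imbalanced stress table, DREAMER-like ECG trials whose latent
# parameters determine the VAD labels, and imbalanced multichannel activity
# windows. All generators are bit-reproducible under a fixed seed.

#' Generate a class-conditional Gaussian stress feature table
#'
#' Emulates a wearable-stress HRV feature table: `n_rows` rows of `n_features`
#' Gaussian features with three imbalanced classes. Each class shifts its mean
#' by `effect_size` (in within-class SD units, which are 1) on a class-specific
#' random subset of half the features, so classes are linearly separable once
#' `effect_size` is large and indistinguishable at `effect_size = 0`.
#' Class counts follow `class_proportions` rounded half away from zero with any
#' remainder assigned to the largest class.
#'
#' @param n_rows number of rows.
#' @param n_features number of feature columns (default 62).
#' @param class_proportions length-3 nonnegative numeric summing to 1.
#' @param effect_size nonnegative between-class mean shift in SD units.
#' @param seed integer seed.
#' @return a [feature_table] with labels in `{0, 1, 2}`.
#' @export
gen_stress_table <- function(n_rows, n_features = 62,
                             class_proportions = c(0.5281, 0.1700, 0.3019),
                             effect_size = 1, seed = 1) {
  if (n_features < 1) stopf("n_features must be >= 1")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  check_prob_triple(class_proportions, "class_proportions")
  set.seed(seed)
  k <- length(class_proportions)
  counts <- allocate_counts(n_rows, class_proportions)
  n_shift <- max(1L, floor(n_features / 2))
  shift_sets <- lapply(seq_len(k), function(i) sample.int(n_features, n_shift))
  values <- matrix(rnorm(n_rows * n_features), n_rows, n_features)
  labels <- rep.int(seq_len(k) - 1L, counts)
  for (c in seq_len(k)) {
    rows <- which(labels == c - 1L)
    if (length(rows) && effect_size > 0)
      values[rows, shift_sets[[c]]] <- values[rows, shift_sets[[c]]] + effect_size
  }
  # shuffle rows so class blocks are not contiguous
  ord <- sample.int(n_rows)
  feature_table(values[ord, , drop = FALSE], labels[ord],
                sprintf("hrv_f%02d", seq_len(n_features)))
}

#' Generate a synthetic single-lead ECG trace
#'
#' A deterministic (seeded) stylized ECG: Gaussian-shaped R-wave pulses placed
#' at RR intervals drawn from Normal(60/heart_rate_bpm, rr_sd_s) truncated to
#' positive values, plus a 0.2 Hz baseline-wander sinusoid and additive white
#' noise. The first R peak sits at t = 0.5 s, which fixes peak counts on
#' integer-second durations. Not a physiological PQRST model; a stand-in with
#' controllable rate, variability and noise.
#'
#' @param duration_s trace duration in seconds.
#' @param rate_hz sampling rate (default 128).
#' @param heart_rate_bpm mean heart rate in beats per minute, in (20, 240).
#' @param rr_sd_s SD of the RR interval in seconds (>= 0).
#' @param noise_sd SD of additive white noise (>= 0).
#' @param seed integer seed.
#' @param wander_amp amplitude of the 0.2 Hz baseline wander (default 0.1).
#' @param r_width_s Gaussian half-width of the R pulse in seconds
#'   (default 0.02, a crisp QRS-like spike).
#' @return numeric vector of length `round(duration_s * rate_hz)`.
#' @export
gen_ecg <- function(duration_s, rate_hz = 128, heart_rate_bpm = 70,
                    rr_sd_s = 0.02, noise_sd = 0.05, seed = 1,
                    wander_amp = 0.1, r_width_s = 0.02) {
  if (duration_s <= 0 || rate_hz <= 0) stopf("duration_s and rate_hz must be > 0")
  if (heart_rate_bpm <= 20 || heart_rate_bpm >= 240)
    stopf("heart_rate_bpm must be in (20, 240)")
  if (rr_sd_s < 0 || noise_sd < 0) stopf("rr_sd_s and noise_sd must be >= 0")
  set.seed(seed)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  rr_mean <- 60 / heart_rate_bpm
  # draw peak times: first at 0.5 s, then cumulative truncated-normal RRs
  peaks <- 0.5
  while (tail(peaks, 1) < duration_s) {
    rr <- rnorm(1, rr_mean, rr_sd_s)
    while (rr <= 0) rr <- rnorm(1, rr_mean, rr_sd_s)
    peaks <- c(peaks, tail(peaks, 1) + rr)
  }
  peaks <- peaks[peaks < duration_s]
  x <- numeric(n)
  sigma <- r_width_s
  for (p in peaks) {
    lo <- max(1L, floor((p - 5 * sigma) * rate_hz) + 1L)
    hi <- min(n, ceiling((p + 5 * sigma) * rate_hz) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] + exp(-((t[idx] - p)^2) / (2 * sigma^2))
  }
  x <- x + wander_amp * sin(2 * pi * 0.2 * t)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  x
}

#' Default affine latent-to-VAD map
#'
#' Maps the generator latents (heart rate, RR variability, noise level) to
#' raw SAM-scale labels in `[1, 5]`: arousal increases with heart rate,
#' valence decreases with noise, and dominance decreases with both RR
#' variability and heart rate (sense of control drops at high activation and
#' high beat-to-beat irregularity). The heart-rate term in dominance keeps
#' that dimension recoverable from aggregate segment features, which are
#' nearly blind to beat-timing variability alone; the weights are
#' configurable. Ranges match the latent sampling ranges of
#' [gen_dreamer_like()].
#'
#' @param label_jitter_sd SD of Gaussian jitter added to the mapped labels
#'   before clipping (default 0: labels are an exact function of the latents).
#' @param dominance_weights nonnegative weights `c(hr, rr_sd)` of the two
#'   dominance drivers (default `c(0.65, 0.35)`).
#' @return an object of class `vad_latent_map` with a `$map(hr, rr_sd, noise_sd)`
#'   function returning a length-3 vector (valence, arousal, dominance).
#' @export
vad_latent_map <- function(label_jitter_sd = 0,
                           dominance_weights = c(0.65, 0.35)) {
  if (label_jitter_sd < 0) stopf("label_jitter_sd must be >= 0")
  ranges <- list(hr = c(45, 130), rr_sd = c(0.005, 0.30), noise = c(0.02, 0.30))
  map <- function(hr, rr_sd, noise_sd) {
    u_hr <- (hr - ranges$hr[1]) / diff(ranges$hr)
    u_rr <- (rr_sd - ranges$rr_sd[1]) / diff(ranges$rr_sd)
    u_nz <- (noise_sd - ranges$noise[1]) / diff(ranges$noise)
    arousal <- 1 + 4 * u_hr
    valence <- 5 - 4 * u_nz
    dominance <- 5 - 4 * (dominance_weights[1] * u_hr +
                            dominance_weights[2] * u_rr)
    pmin(5, pmax(1, c(valence, arousal, dominance)))
  }
  structure(list(map = map, ranges = ranges, label_jitter_sd = label_jitter_sd),
            class = "vad_latent_map")
}

#' Generate a DREAMER-like trial set
#'
#' Per trial, latents (heart rate, RR SD, noise SD) are drawn uniformly from
#' the map's ranges, an ECG trace is synthesized with [gen_ecg()], and the raw
#' VAD labels are `map(latents)` plus optional jitter, clipped to `[1, 5]`.
#'
#' @param n_subjects,trials_per_subject counts (defaults 23 and 18, the sizes
#'   of the emulated study).
#' @param trial_duration_s trial length in seconds (default 61.25, which gives
#'   23 five-second windows at 50% overlap and 128 Hz).
#' @param map a [vad_latent_map()].
#' @param seed integer seed.
#' @param rate_hz sampling rate (default 128).
#' @return a [trial_set]; each trial carries its latents in `$latents`.
#' @export
gen_dreamer_like <- function(n_subjects = 23, trials_per_subject = 18,
                             trial_duration_s = 61.25,
                             map = vad_latent_map(), seed = 1, rate_hz = 128) {
  set.seed(seed)
  r <- map$ranges
  trials <- list()
  for (s in seq_len(n_subjects)) {
    for (tr in seq_len(trials_per_subject)) {
      hr <- runif(1, r$hr[1], r$hr[2])
      rr <- runif(1, r$rr_sd[1], r$rr_sd[2])
      nz <- runif(1, r$noise[1], r$noise[2])
      ecg_seed <- sample.int(.Machine$integer.max - 1L, 1)
      vad <- map$map(hr, rr, nz)
      if (map$label_jitter_sd > 0)
        vad <- pmin(5, pmax(1, vad + rnorm(3, 0, map$label_jitter_sd)))
      trials[[length(trials) + 1L]] <- list(
        subject_id = sprintf("S%02d", s), trial_id = tr,
        ecg = gen_ecg(trial_duration_s, rate_hz, hr, rr, nz, seed = ecg_seed),
        vad_raw = vad,
        latents = c(hr = hr, rr_sd = rr, noise_sd = nz))
    }
  }
  trial_set(trials)
}

#' Generate imbalanced multichannel activity windows
#'
#' Class-conditional multichannel windows for the activity-recognition path:
#' class `c` has a distinct dominant oscillation frequency and amplitude,
#' both scaled by `effect_size`, plus unit white noise. Counts follow
#' `proportions` with rounding remainder to the largest class. The default
#' proportions reproduce the 12137 : 969 : 699 : 131 imbalance profile of the
#' emulated activity data.
#'
#' @param n_total number of windows.
#' @param proportions class proportions (default the 4-class imbalance above).
#' @param window_samples samples per window.
#' @param n_channels channels per window.
#' @param effect_size nonnegative class-signal scale; 0 means pure noise.
#' @param seed integer seed.
#' @return list with `windows` (array n x window_samples x n_channels) and
#'   `labels` (integer vector in `{0..k-1}`).
#' @export
gen_activity_windows <- function(n_total,
                                 proportions = c(12137, 969, 699, 131) / 13936,
                                 window_samples = 256, n_channels = 3,
                                 effect_size = 1, seed = 1) {
  if (effect_size < 0) stopf("effect_size must be >= 0")
  proportions <- proportions / sum(proportions)
  set.seed(seed)
  k <- length(proportions)
  counts <- allocate_counts(n_total, proportions)
  labels <- rep.int(seq_len(k) - 1L, counts)
  cycles <- c(4, 8, 16, 32)[seq_len(k)]          # dominant cycles per window
  amps <- (1 + 0.3 * (seq_len(k) - 1))           # per-class amplitude
  tt <- (seq_len(window_samples) - 1) / window_samples
  x <- array(rnorm(n_total * window_samples * n_channels),
             dim = c(n_total, window_samples, n_channels))
  if (effect_size > 0) {
    for (i in seq_len(n_total)) {
      c <- labels[i] + 1L
      for (ch in seq_len(n_channels)) {
        phase <- runif(1, 0, 2 * pi)
        x[i, , ch] <- x[i, , ch] +
          effect_size * amps[c] * sin(2 * pi * cycles[c] * tt + phase)
      }
    }
  }
  ord <- sample.int(n_total)
  list(windows = x[ord, , , drop = FALSE], labels = labels[ord])
}
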
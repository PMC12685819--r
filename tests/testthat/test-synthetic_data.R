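test_that("stress-table class counts follow the requested proportions", {
  tab <- gen_stress_table(135650, n_features = 6,
                          class_proportions = c(0.5281, 0.1700, 0.3019),
                          seed = 7)
  counts <- as.integer(table(tab$labels))
  expect_true(all(abs(counts - c(71636, 23061, 40953)) <= 1))
  expect_identical(sum(counts), 135650L)
})

test_that("zero effect size gives statistically indistinguishable classes", {
  tab <- gen_stress_table(1000, 8, effect_size = 0, seed = 11)
  for (j in c(1, 4, 8)) {
    p <- t.test(tab$values[tab$labels == 0, j],
                tab$values[tab$labels == 1, j])$p.value
    expect_gt(p, 0.001)
  }
})

test_that("a large effect size makes classes linearly separable", {
  tab <- gen_stress_table(3000, 62, effect_size = 3, seed = 13)
  idx <- seq_len(2400)
  fit <- MASS::lda(tab$values[idx, ], grouping = tab$labels[idx])
  pred <- predict(fit, tab$values[-idx, ])$class
  expect_gte(mean(pred == tab$labels[-idx]), 0.95)
})

test_that("noise-free ECG at 60 bpm places ten peaks in ten seconds", {
  x <- gen_ecg(10, 128, heart_rate_bpm = 60, rr_sd_s = 0, noise_sd = 0,
               wander_amp = 0, seed = 1)
  expect_length(find_peaks(x), 10)  # first peak at 0.5 s, then every second
})

test_that("peak detection recovers the requested heart rate within 1%", {
  x <- gen_ecg(60, 128, heart_rate_bpm = 120, rr_sd_s = 0.01, noise_sd = 0,
               wander_amp = 0, seed = 5)
  pk <- find_peaks(x) / 128
  expect_lt(abs(mean(diff(pk)) - 0.5) / 0.5, 0.01)
})

test_that("all generators are reproducible under a fixed seed", {
  expect_identical(gen_ecg(5, seed = 9), gen_ecg(5, seed = 9))
  t1 <- gen_stress_table(200, 5, seed = 2)
  t2 <- gen_stress_table(200, 5, seed = 2)
  expect_identical(t1$values, t2$values)
  a1 <- gen_activity_windows(100, seed = 3)
  a2 <- gen_activity_windows(100, seed = 3)
  expect_identical(a1$windows, a2$windows)
  d1 <- gen_dreamer_like(1, 2, trial_duration_s = 2, seed = 4)
  d2 <- gen_dreamer_like(1, 2, trial_duration_s = 2, seed = 4)
  expect_identical(d1$trials[[2]]$ecg, d2$trials[[2]]$ecg)
})

test_that("the full study layout yields 414 trials of the right length", {
  ts <- gen_dreamer_like(23, 18, trial_duration_s = 1, seed = 1)
  expect_length(ts$trials, 414)
  expect_length(ts$trials[[1]]$ecg, 128)
})

test_that("zero label jitter makes VAD an exact function of the latents", {
  map <- vad_latent_map(label_jitter_sd = 0)
  ts <- gen_dreamer_like(2, 4, trial_duration_s = 2, map = map, seed = 6)
  for (tr in ts$trials) {
    expected <- map$map(tr$latents["hr"], tr$latents["rr_sd"],
                        tr$latents["noise_sd"])
    expect_equal(unname(tr$vad_raw), unname(expected), tolerance = 1e-12)
  }
})

test_that("a 61.25-second trial at 128 Hz segments into 23 windows", {
  ts <- gen_dreamer_like(1, 1, trial_duration_s = 61.25, seed = 2)
  segs <- segment_signal(ts$trials[[1]]$ecg, 640, 320)
  expect_identical(nrow(segs), 23L)
})

test_that("activity-window counts follow the imbalance profile", {
  aw <- gen_activity_windows(1394, seed = 8, window_samples = 32)
  expect_identical(as.integer(table(aw$labels)), c(1214L, 97L, 70L, 13L))
  expect_identical(dim(aw$windows), c(1394L, 32L, 3L))
})

test_that("spectral content separates class 0 once the effect is large", {
  aw <- gen_activity_windows(400, proportions = rep(0.25, 4),
                             window_samples = 64, n_channels = 1,
                             effect_size = 4, seed = 9)
  centroid <- apply(aw$windows[, , 1], 1, function(w) {
    p <- Mod(fft(w))[2:32]^2
    sum((1:31) * p) / sum(p)
  })
  # class 0 oscillates at 4 cycles per window, the others at 8+; a centroid
  # threshold at the midpoint (6 cycles) separates class 0 from the rest
  pred0 <- centroid < 6
  expect_gte(mean(pred0 == (aw$labels == 0)), 0.95)
})

test_that("zero effect size leaves no class/frequency association", {
  aw <- gen_activity_windows(400, proportions = rep(0.25, 4),
                             window_samples = 64, n_channels = 1,
                             effect_size = 0, seed = 10)
  centroid <- apply(aw$windows[, , 1], 1, function(w) {
    p <- Mod(fft(w))[2:32]^2
    sum((1:31) * p) / sum(p)
  })
  p <- summary(aov(centroid ~ factor(aw$labels)))[[1]][["Pr(>F)"]][1]
  expect_gt(p, 0.01)
})
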
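test_that("metadata columns are dropped, absent names warn, emptying errors", {
  tab <- feature_table(matrix(rnorm(5 * 64), 5, 64), rep(0:1, length.out = 5),
                       c(paste0("f", 1:62), "subject id", "condition"))
  out <- drop_nonfeature_columns(tab, c("subject id", "condition"))
  expect_identical(ncol(out$values), 62L)
  expect_identical(out$column_names, paste0("f", 1:62))
  expect_warning(out2 <- drop_nonfeature_columns(tab, "SSSQ class"),
                 "not present")
  expect_identical(dim(out2$values), dim(tab$values))
  expect_error(drop_nonfeature_columns(out, out$column_names), "zero feature")
})

test_that("z-scoring matches the population-SD hand computation", {
  params <- zscore_fit(matrix(c(1, 2, 3), 3, 1))
  expect_equal(params$mu, 2, ignore_attr = TRUE)
  expect_equal(params$sigma, sqrt(2 / 3), ignore_attr = TRUE, tolerance = 1e-12)
  z <- zscore_apply(matrix(c(1, 2, 3), 3, 1), params)
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
})

test_that("fit-then-apply standardizes the fit set to mean 0, SD 1", {
  set.seed(31)
  x <- matrix(rnorm(200 * 7, mean = 5, sd = 3), 200, 7)
  z <- zscore_apply(x, zscore_fit(x))
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(z^2) - colMeans(z)^2) - 1) < 1e-9))
})

test_that("constant features and dimension mismatches are rejected", {
  x <- cbind(rnorm(10), rep(2, 10))
  expect_error(zscore_fit(x), "constant feature")
  p <- zscore_fit(matrix(rnorm(20), 10, 2))
  expect_error(zscore_apply(matrix(rnorm(30), 10, 3), p), "mismatch")
})

test_that("the two-stage split reproduces the printed 70/15/15 sizes", {
  tab <- gen_stress_table(135650, n_features = 2, seed = 5)
  sp <- stratified_split(tab, seed = 5, stratified = FALSE)
  expect_identical(nrow(sp$train$values), 94955L)
  expect_identical(nrow(sp$val$values), 20347L)
  expect_identical(nrow(sp$test$values), 20348L)
})

test_that("stratified splitting partitions rows and preserves proportions", {
  tab <- gen_stress_table(400, 3, class_proportions = c(0.5, 0.3, 0.2), seed = 9)
  sp <- stratified_split(tab, seed = 9)
  idx <- c(sp$indices$train, sp$indices$val, sp$indices$test)
  expect_identical(sort(idx), seq_len(400))          # partition, no duplicates
  for (part in list(sp$train, sp$val, sp$test)) {
    n <- length(part$labels)
    for (c in 0:2) {
      expected <- mean(tab$labels == c) * n
      expect_lte(abs(sum(part$labels == c) - expected), 1)
    }
  }
})

test_that("too-small classes cannot be stratified", {
  tab <- feature_table(matrix(rnorm(10), 5, 2), c(0L, 0L, 0L, 1L, 1L))
  expect_error(stratified_split(tab), ">= 3 rows")
})

test_that("window counts follow floor((N - W) / S) + 1", {
  x <- seq_len(7680)
  w <- segment_signal(x, 640, 320)
  expect_identical(nrow(w), 23L)
  expect_equal(w[1, ], as.numeric(x[1:640]))
  expect_equal(w[2, 1], 321)
  expect_identical(nrow(segment_signal(seq_len(640), 640, 320)), 1L)
  expect_error(segment_signal(seq_len(639), 640, 320), "shorter")
  set.seed(17)
  for (r in 1:25) {
    W <- sample(4:64, 1); S <- sample(W, 1); N <- W + sample(0:200, 1)
    expect_identical(nrow(segment_signal(seq_len(N), W, S)),
                     as.integer(floor((N - W) / S) + 1))
  }
})

test_that("windows inherit the parent trial's labels with provenance", {
  rows <- inherit_labels(c(3, 4, 2), 23, "S05", 7L)
  expect_identical(nrow(rows), 23L)
  expect_true(all(rows$valence == 3 & rows$arousal == 4 & rows$dominance == 2))
  expect_true(all(rows$trial_id == 7L & rows$subject_id == "S05"))
  expect_identical(nrow(inherit_labels(c(1, 1, 1), 0)), 0L)
})

test_that("a 50 Hz notch removes a 50 Hz tone almost entirely", {
  fs <- 500
  x <- sin(2 * pi * 50 * (0:(30 * fs - 1)) / fs)
  rec <- signal_record(matrix(x, 1), fs)
  out <- apply_filter(rec, "notch", center_hz = 50, Q = 30)
  expect_identical(dim(out$data), dim(rec$data))
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(x^2)), 0.05)
})

test_that("a generous band-pass passes an in-band signal unchanged", {
  fs <- 128
  x <- sin(2 * pi * 8 * (0:(20 * fs - 1)) / fs) +
    0.5 * sin(2 * pi * 15 * (0:(20 * fs - 1)) / fs)
  rec <- signal_record(matrix(x, 1), fs)
  out <- apply_filter(rec, "butterworth_bandpass", band_hz = c(1, 40))
  expect_gt(cor(as.numeric(out$data), x), 0.99)
})

test_that("bands at or above Nyquist are rejected", {
  rec <- signal_record(matrix(rnorm(256), 1), 128)
  expect_error(apply_filter(rec, "butterworth_bandpass", band_hz = c(10, 70)),
               "Nyquist")
  expect_error(apply_filter(rec, "notch", center_hz = 64), "Nyquist")
})

test_that("VAD normalization maps the 1-5 scale onto [0, 1]", {
  expect_equal(normalize_vad(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(normalize_vad(c(5, 5, 5)), c(1, 1, 1))
  expect_error(normalize_vad(c(0.5, 3, 4)), "\\[1, 5\\]")
  expect_equal(denormalize_vad(normalize_vad(c(2.2, 3.7, 4.9))),
               c(2.2, 3.7, 4.9), tolerance = 1e-12)
})
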
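test_that("statistical features match the hand-computed example", {
  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(unname(f[c("stat_mean", "stat_median", "stat_min", "stat_max",
                          "stat_range")]), c(2.5, 2.5, 1, 4, 3))
  expect_equal(unname(f["stat_rms"]), sqrt(7.5), tolerance = 1e-12)
})

test_that("a constant segment degenerates to the documented conventions", {
  f <- statistical_features(rep(3.7, 100))
  expect_equal(unname(f[c("stat_sd", "stat_iqr", "stat_skewness",
                          "stat_kurtosis", "stat_entropy")]), rep(0, 5))
})

test_that("statistical features are permutation invariant", {
  set.seed(41)
  seg <- rnorm(200)
  expect_equal(statistical_features(seg),
               statistical_features(sample(seg)), tolerance = 1e-12)
})

test_that("entropy respects its bounds and the uniform maximum", {
  expect_equal(shannon_entropy(rep(1, 50)), 0)
  # 16 values hitting 16 distinct bins equally
  expect_equal(shannon_entropy(seq(0, 15.999, length.out = 16)), 4)
  set.seed(42)
  for (r in 1:20) expect_lte(shannon_entropy(rnorm(100)), log2(16))
})

test_that("wavelet features are zero for zero input and homogeneous", {
  expect_equal(unname(wavelet_features(numeric(640))), rep(0, 12))
  set.seed(43)
  seg <- rnorm(640)
  f1 <- wavelet_features(seg)
  f3 <- wavelet_features(3 * seg)
  expect_equal(unname(f3), unname(3 * f1), tolerance = 1e-10)
})

test_that("the DWT agrees with a direct convolution-and-downsample oracle", {
  set.seed(44)
  seg <- rnorm(640)
  mine <- dwt_db4(seg, 3)
  theirs <- oracle_dwt_db4(seg, 3)
  for (b in 1:4) expect_equal(unname(mine[[b]]), theirs[[b]], tolerance = 1e-8)
})

test_that("too-short segments are rejected by the wavelet extractor", {
  expect_error(dwt_db4(rnorm(6), 3), "too short")
})

test_that("STFT features localize a pure tone in its bin", {
  seg <- sin(2 * pi * 3 * (0:639) / 64)     # bin-3 center frequency
  f <- stft_features(seg)
  expect_identical(unname(which.max(f)), 4L)  # index 4 is bin 3 (0-based)
  expect_equal(unname(stft_features(numeric(640))), rep(0, 10))
  expect_length(stft_features(rnorm(64)), 10)
  expect_length(stft_features(rnorm(1000)), 10)
  expect_error(stft_features(rnorm(63)), "shorter")
})

test_that("the 33-vector is the documented concatenation", {
  set.seed(45)
  seg <- rnorm(640)
  f <- extract_features(seg)
  expect_length(f, 33)
  expect_identical(names(f), feature_names_33())
  expect_equal(unname(f[1:11]), unname(statistical_features(seg)))
  expect_equal(unname(f[12:23]), unname(wavelet_features(seg)))
  expect_equal(unname(f[24:33]), unname(stft_features(seg)))
})

test_that("every feature matches the naive-loop oracle on random segments", {
  set.seed(46)
  for (r in 1:100) {
    seg <- rnorm(sample(c(64, 128, 640), 1), sd = runif(1, 0.5, 3))
    expect_equal(unname(extract_features(seg)), oracle_features_33(seg),
                 tolerance = 1e-9)
  }
})

test_that("batch extraction equals the per-segment loop", {
  set.seed(47)
  segs <- matrix(rnorm(5 * 640), 5, 640)
  batch <- extract_features_batch(segs)
  expect_identical(dim(batch), c(5L, 33L))
  for (i in 1:5)
    expect_equal(unname(batch[i, ]), unname(extract_features(segs[i, ])),
                 tolerance = 1e-10)
})

test_that("wavelet and STFT features are order sensitive, unlike statistics", {
  ramp <- seq(0, 1, length.out = 640)
  set.seed(48)
  shuffled <- sample(ramp)
  expect_equal(statistical_features(ramp), statistical_features(shuffled),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(wavelet_features(ramp),
                                wavelet_features(shuffled))))
  expect_false(isTRUE(all.equal(stft_features(ramp), stft_features(shuffled))))
})

test_that("scaling the input scales the amplitude features by |c|", {
  set.seed(49)
  seg <- rnorm(640)
  f1 <- extract_features(seg)
  f2 <- extract_features(-2 * seg)
  amp <- c("stat_sd", "stat_iqr", "stat_range", "stat_rms")
  expect_equal(unname(f2[amp]), unname(2 * f1[amp]), tolerance = 1e-10)
  expect_equal(unname(f2["stat_mean"]), unname(-2 * f1["stat_mean"]),
               tolerance = 1e-10)
  # entropy depends only on the bin-occupancy pattern, which is unchanged
  expect_equal(unname(f2["stat_entropy"]), unname(f1["stat_entropy"]),
               tolerance = 1e-10)
})
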
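# 33-feature extractor for ECG segments: 11 statistical + 12 wavelet (db4,
# 3 levels) + 10 STFT band powers, concatenated in a fixed, named order.

# Daubechies-4 analysis low-pass filter (8 taps, standard published values).
.db4_dec_lo <- c(-0.010597401784997278, 0.032883011666982945,
                 0.030841381835986965, -0.18703481171888114,
                 -0.02798376941698385, 0.6308807679295904,
                 0.7148465705525415, 0.23037781330885523)
# quadrature mirror: hi[k] = (-1)^(k+1) * lo[L-1-k] (k zero-based)
.db4_dec_hi <- {
  L <- length(.db4_dec_lo)
  k <- seq_len(L) - 1
  (-1)^(k + 1) * .db4_dec_lo[L - k]
}

#' Names of the 33 extracted features, in output order
#' @return character vector of length 33.
#' @export
feature_names_33 <- function() {
  c(paste0("stat_", c("mean", "median", "sd", "iqr", "skewness", "kurtosis",
                      "min", "max", "range", "rms", "entropy")),
    paste0("wav_", rep(c("a3", "d3", "d2", "d1"), each = 3), "_",
           rep(c("mean", "sd", "rms"), 4)),
    paste0("stft_band", 0:9))
}

#' Shannon entropy of a segment's amplitude histogram
#'
#' Histogram over the segment's own `[min, max]` with `n_bins` equal-width
#' bins (a constant signal occupies a single bin), probabilities
#' `p = counts / n`, and `H = -sum p log2 p` with `0 log 0 := 0`. Bounded by
#' `log2(n_bins)` bits.
#'
#' @param segment numeric vector (length >= 1).
#' @param n_bins number of histogram bins (default 16, >= 2).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(segment, n_bins = 16) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  if (length(segment) < 1) stopf("empty segment")
  lo <- min(segment); hi <- max(segment)
  if (hi == lo) return(0)
  bins <- pmin(n_bins, floor((segment - lo) / (hi - lo) * n_bins) + 1L)
  p <- tabulate(bins, n_bins) / length(segment)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' The 11 statistical features of a segment
#'
#' In order: mean, median, SD, IQR, skewness, excess kurtosis, min, max,
#' range, RMS, Shannon entropy. Moments use the population convention
#' (skewness `m3 / m2^1.5`, excess kurtosis `m4 / m2^2 - 3`); the IQR uses
#' linear-interpolation percentiles; a constant segment gets skewness and
#' kurtosis 0 by convention.
#'
#' @param segment numeric vector of length >= 2.
#' @param entropy_bins histogram bins for the entropy term (default 16).
#' @return named numeric vector of length 11.
#' @export
statistical_features <- function(segment, entropy_bins = 16) {
  n <- length(segment)
  if (n < 2) stopf("segment must have length >= 2")
  m <- mean(segment)
  d <- segment - m
  m2 <- mean(d^2)
  skew <- if (m2 == 0) 0 else mean(d^3) / m2^1.5
  kurt <- if (m2 == 0) 0 else mean(d^4) / m2^2 - 3
  q <- stats::quantile(segment, c(0.25, 0.75), names = FALSE, type = 7)
  out <- c(m, stats::median(segment), sqrt(m2), q[2] - q[1], skew, kurt,
           min(segment), max(segment), max(segment) - min(segment),
           sqrt(mean(segment^2)), shannon_entropy(segment, entropy_bins))
  names(out) <- feature_names_33()[1:11]
  out
}

# one analysis step of the pyramid: symmetric (repeat-edge) extension by
# L-1 samples each side, full convolution, keep every second sample starting
# at index L+1 (1-based); output length floor((n + L - 1) / 2).
.dwt_step <- function(x, filt) {
  L <- length(filt)
  n <- length(x)
  ext <- c(rev(x[seq_len(L - 1)]), x, rev(x[(n - L + 2):n]))
  full <- stats::convolve(ext, rev(filt), type = "open")
  out_len <- floor((n + L - 1) / 2)
  full[seq(L + 1, by = 2, length.out = out_len)]
}

#' Multilevel discrete wavelet decomposition (db4)
#'
#' Pyramid analysis with the Daubechies-4 filter pair, symmetric repeat-edge
#' extension, and even-index downsampling (coefficient lengths
#' `floor((n + 7) / 2)` per level, matching the common filter-bank
#' convention).
#'
#' @param segment numeric vector.
#' @param levels decomposition depth (default 3).
#' @return list of coefficient vectors, deepest approximation first:
#'   `A<levels>, D<levels>, ..., D1`.
#' @export
dwt_db4 <- function(segment, levels = 3) {
  min_len <- 2^levels
  if (length(segment) < min_len)
    stopf("segment (%d) too short for a %d-level decomposition", length(segment), levels)
  details <- list()
  approx <- segment
  for (l in seq_len(levels)) {
    details[[l]] <- .dwt_step(approx, .db4_dec_hi)
    approx <- .dwt_step(approx, .db4_dec_lo)
  }
  out <- c(list(approx), rev(details))
  names(out) <- c(sprintf("A%d", levels), sprintf("D%d", levels:1))
  out
}

#' The 12 wavelet features of a segment
#'
#' db4 decomposition to level 3; for each sub-band in the order A3, D3, D2, D1
#' the mean, SD (population) and RMS energy
#' (`sqrt(mean(coefficients^2))`) of the coefficients.
#'
#' @param segment numeric vector (length >= 8).
#' @return named numeric vector of length 12.
#' @export
wavelet_features <- function(segment) {
  bands <- dwt_db4(segment, 3)
  out <- unlist(lapply(bands, function(cf)
    c(mean(cf), pop_sd(cf), sqrt(mean(cf^2)))), use.names = FALSE)
  names(out) <- feature_names_33()[12:23]
  out
}

#' Short-time Fourier transform of a segment
#'
#' Hann-windowed (periodic window) frames of `nperseg` samples with 50%
#' overlap, no padding (an incomplete tail frame is dropped), one-sided
#' spectrum.
#'
#' @param segment numeric vector of length >= `nperseg`.
#' @param nperseg frame length (default 64).
#' @return complex matrix, frames x frequency bins (`nperseg/2 + 1` bins).
#' @export
stft <- function(segment, nperseg = 64) {
  n <- length(segment)
  if (n < nperseg) stopf("segment (%d) shorter than nperseg (%d)", n, nperseg)
  hop <- nperseg %/% 2
  n_frames <- floor((n - nperseg) / hop) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1) / nperseg)
  n_bins <- nperseg %/% 2 + 1
  out <- matrix(0i, n_frames, n_bins)
  for (f in seq_len(n_frames)) {
    frame <- segment[(f - 1) * hop + seq_len(nperseg)] * w
    out[f, ] <- stats::fft(frame)[seq_len(n_bins)]
  }
  out
}

#' The 10 STFT band-power features of a segment
#'
#' Mean over time frames of the power (squared magnitude by default) in each
#' of the 10 lowest frequency bins of a 64-sample Hann STFT at 50% overlap.
#'
#' @param segment numeric vector of length >= `nperseg`.
#' @param nperseg STFT frame length (default 64).
#' @param use_magnitude if TRUE use `|X|` instead of `|X|^2` as "power".
#' @return named numeric vector of length 10.
#' @export
stft_features <- function(segment, nperseg = 64, use_magnitude = FALSE) {
  s <- stft(segment, nperseg)
  p <- if (use_magnitude) Mod(s) else Mod(s)^2
  out <- colMeans(p[, 1:10, drop = FALSE])
  names(out) <- feature_names_33()[24:33]
  out
}

#' Extract the full 33-value feature vector of an ECG segment
#'
#' Concatenation of [statistical_features()] (11), [wavelet_features()] (12)
#' and [stft_features()] (10), in that fixed order; see [feature_names_33()].
#'
#' @param segment numeric vector valid for all three extractors
#'   (length >= 64 with the defaults; the standard 640-sample 5-s window at
#'   128 Hz always is).
#' @param entropy_bins,stft_nperseg,stft_use_magnitude tuning knobs passed on.
#' @return named numeric vector of length 33.
#' @export
extract_features <- function(segment, entropy_bins = 16, stft_nperseg = 64,
                             stft_use_magnitude = FALSE) {
  c(statistical_features(segment, entropy_bins),
    wavelet_features(segment),
    stft_features(segment, stft_nperseg, stft_use_magnitude))
}

#' Extract features for a batch of segments
#'
#' @param segments numeric matrix, one segment per row.
#' @param ... passed to [extract_features()].
#' @return numeric matrix, rows x 33, with feature column names.
#' @export
extract_features_batch <- function(segments, ...) {
  out <- t(apply(segments, 1, extract_features, ...))
  colnames(out) <- feature_names_33()
  out
}
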
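# Independent naive-loop oracles for the feature extractor, plus small
# shared utilities for the model tests. These deliberately avoid the
# package's vectorized code paths.

oracle_stat_features <- function(seg, n_bins = 16) {
  n <- length(seg)
  mu <- sum(seg) / n
  m2 <- sum((seg - mu)^2) / n
  m3 <- sum((seg - mu)^3) / n
  m4 <- sum((seg - mu)^4) / n
  srt <- sort(seg)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  # linear-interpolation percentile (type 7): h = (n-1)p + 1
  pct <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    srt[lo] + (h - lo) * (srt[min(lo + 1, n)] - srt[lo])
  }
  # histogram entropy, equal-width bins over [min, max]
  lo <- min(seg); hi <- max(seg)
  ent <- if (hi == lo) 0 else {
    counts <- numeric(n_bins)
    for (v in seg) {
      b <- floor((v - lo) / (hi - lo) * n_bins) + 1
      if (b > n_bins) b <- n_bins
      counts[b] <- counts[b] + 1
    }
    p <- counts / n
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  c(mu, med, sqrt(m2), pct(0.75) - pct(0.25),
    if (m2 == 0) 0 else m3 / m2^1.5,
    if (m2 == 0) 0 else m4 / m2^2 - 3,
    min(seg), max(seg), max(seg) - min(seg),
    sqrt(sum(seg^2) / n), ent)
}

# direct convolution-and-downsample DWT step, written as explicit loops
# over the documented convention: repeat-edge extension by L-1, full
# convolution, keep samples L+1, L+3, ... (1-based)
oracle_dwt_step <- function(x, filt) {
  L <- length(filt)
  n <- length(x)
  ext <- c(rev(x[1:(L - 1)]), x, rev(x[(n - L + 2):n]))
  ne <- length(ext)
  full <- numeric(ne + L - 1)
  for (k in seq_along(full)) {
    s <- 0
    for (j in seq_len(L)) {
      idx <- k - j + 1
      if (idx >= 1 && idx <= ne) s <- s + filt[j] * ext[idx]
    }
    full[k] <- s
  }
  out_len <- floor((n + L - 1) / 2)
  out <- numeric(out_len)
  for (i in seq_len(out_len)) out[i] <- full[L + 1 + 2 * (i - 1)]
  out
}

oracle_dwt_db4 <- function(seg, levels = 3) {
  lo <- affectkit:::.db4_dec_lo
  hi <- affectkit:::.db4_dec_hi
  details <- list()
  a <- seg
  for (l in seq_len(levels)) {
    details[[l]] <- oracle_dwt_step(a, hi)
    a <- oracle_dwt_step(a, lo)
  }
  c(list(a), rev(details))
}

oracle_wavelet_features <- function(seg) {
  bands <- oracle_dwt_db4(seg, 3)
  out <- numeric(0)
  for (cf in bands) {
    n <- length(cf)
    mu <- sum(cf) / n
    out <- c(out, mu, sqrt(sum((cf - mu)^2) / n), sqrt(sum(cf^2) / n))
  }
  out
}

oracle_stft_features <- function(seg, nperseg = 64) {
  n <- length(seg)
  hop <- nperseg / 2
  n_frames <- floor((n - nperseg) / hop) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / nperseg)
  acc <- numeric(10)
  for (f in seq_len(n_frames)) {
    frame <- seg[(f - 1) * hop + 1:nperseg] * w
    for (k in 0:9) {
      # direct DFT bin k
      ex <- exp(-2i * pi * k * (0:(nperseg - 1)) / nperseg)
      acc[k + 1] <- acc[k + 1] + Mod(sum(frame * ex))^2
    }
  }
  acc / n_frames
}

oracle_features_33 <- function(seg) {
  c(oracle_stat_features(seg), oracle_wavelet_features(seg),
    oracle_stft_features(seg))
}

# central finite-difference gradient of a scalar loss wrt one parameter entry
numeric_param_grad <- function(model, x, y, li, pn, idx, lossfun, eps = 1e-5) {
  m1 <- model
  m1$layers[[li]]$params[[pn]][idx] <- m1$layers[[li]]$params[[pn]][idx] + eps
  m2 <- model
  m2$layers[[li]]$params[[pn]][idx] <- m2$layers[[li]]$params[[pn]][idx] - eps
  (lossfun(m1, x, y) - lossfun(m2, x, y)) / (2 * eps)
}

# mean silhouette width of a 2-cluster labeling in a 2D embedding
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(d[i, labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# simple local-maximum peak finder for the ECG generator tests
find_peaks <- function(x, min_height = 0.5) {
  n <- length(x)
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
          x[2:(n - 1)] > min_height) + 1
}
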
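# Front half of both pipelines: column dropping, z-score normalization
# (standard-scaler, population SD), stratified 70/15/15 splitting, fixed-length
# windowing with overlap, label inheritance, and zero-phase filtering.
# VAD vectors are ordered (valence, arousal, dominance) package-wide.

#' Drop non-feature columns from a feature table
#'
#' Removes metadata columns (subject ids, condition labels, ...) before
#' modeling. Absent names are skipped with a warning; the order of the
#' remaining columns is preserved.
#'
#' @param table a [feature_table].
#' @param names character vector of column names to drop.
#' @return the reduced [feature_table].
#' @export
drop_nonfeature_columns <- function(table, names) {
  missing <- setdiff(names, table$column_names)
  if (length(missing))
    warnf("columns not present, skipped: %s", paste(missing, collapse = ", "))
  keep <- !(table$column_names %in% names)
  if (!any(keep)) stopf("dropping these columns would leave zero feature columns")
  feature_table(table$values[, keep, drop = FALSE], table$labels,
                table$column_names[keep])
}

#' Fit z-score (standard-scaler) parameters
#'
#' Per-feature mean and population SD (divide by n). Errors on a constant
#' feature, whose SD of zero would make the transform undefined.
#'
#' @param data numeric matrix (rows x features).
#' @return list with `mu` and `sigma` vectors, class `zscore_params`.
#' @export
zscore_fit <- function(data) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (nrow(data) < 2) stopf("need >= 2 rows to fit z-score parameters")
  mu <- colMeans(data)
  sigma <- sqrt(colMeans(sweep(data, 2, mu)^2))
  if (any(sigma == 0))
    stopf("constant feature(s) at column(s): %s",
          paste(which(sigma == 0), collapse = ", "))
  structure(list(mu = mu, sigma = sigma), class = "zscore_params")
}

#' Apply fitted z-score parameters
#'
#' @param data numeric matrix with the same number of columns as at fit time.
#' @param params a `zscore_params` object from [zscore_fit()].
#' @return the standardized matrix `(X - mu) / sigma`.
#' @export
zscore_apply <- function(data, params) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (ncol(data) != length(params$mu))
    stopf("dimension mismatch: data has %d columns, params expect %d",
          ncol(data), length(params$mu))
  sweep(sweep(data, 2, params$mu), 2, params$sigma, "/")
}

#' Z-score a single signal trace
#'
#' Per-signal standardization (each trace centered and scaled by its own mean
#' and population SD), the convention for the ECG regression path where every
#' trial is normalized independently.
#'
#' @param x numeric vector.
#' @return standardized vector.
#' @export
zscore_signal <- function(x) {
  s <- pop_sd(x)
  if (s == 0) stopf("constant signal cannot be z-scored")
  (x - mean(x)) / s
}

# allocate `total` slots across classes proportionally to their sizes,
# floor + largest fractional remainder; deterministic.
.alloc_proportional <- function(sizes, total) {
  ideal <- sizes / sum(sizes) * total
  take <- floor(ideal)
  rem <- total - sum(take)
  if (rem > 0) {
    ord <- order(ideal - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  as.integer(take)
}

#' Two-stage stratified train/validation/test split
#'
#' Stage 1 holds out `floor(train_frac * n)` rows for training; stage 2 splits
#' the remainder, validation taking the floor of one half and test the rest
#' (so a 135,650-row table yields 94,955 / 20,347 / 20,348 at 70/15/15).
#' When stratified, per-class allocations use largest-remainder rounding so
#' class proportions are preserved within one row per class per part.
#'
#' @param table a [feature_table].
#' @param train_frac,val_frac,test_frac fractions summing to 1
#'   (defaults 0.70 / 0.15 / 0.15).
#' @param stratified preserve label proportions per part (default TRUE).
#' @param seed integer seed for the shuffles.
#' @return list with `train`, `val`, `test` ([feature_table]s) and `indices`.
#' @export
stratified_split <- function(table, train_frac = 0.70, val_frac = 0.15,
                             test_frac = 0.15, stratified = TRUE, seed = 1) {
  fr <- c(train_frac, val_frac, test_frac)
  if (abs(sum(fr) - 1) > 1e-9) stopf("split fractions must sum to 1")
  n <- nrow(table$values)
  n_train <- floor(train_frac * n)
  rest <- n - n_train
  n_val <- floor(rest * val_frac / (val_frac + test_frac))
  set.seed(seed)
  if (stratified) {
    classes <- sort(unique(table$labels))
    sizes <- vapply(classes, function(c) sum(table$labels == c), 0L)
    if (any(sizes < 3)) stopf("every class needs >= 3 rows for a stratified split")
    tr_alloc <- .alloc_proportional(sizes, n_train)
    idx_tr <- integer(0); idx_rest <- integer(0)
    for (i in seq_along(classes)) {
      rows <- sample(which(table$labels == classes[i]))
      idx_tr <- c(idx_tr, rows[seq_len(tr_alloc[i])])
      idx_rest <- c(idx_rest, rows[-seq_len(tr_alloc[i])])
    }
    rest_sizes <- vapply(classes, function(c) sum(table$labels[idx_rest] == c), 0L)
    val_alloc <- .alloc_proportional(rest_sizes, n_val)
    idx_val <- integer(0); idx_te <- integer(0)
    for (i in seq_along(classes)) {
      rows <- idx_rest[table$labels[idx_rest] == classes[i]]
      idx_val <- c(idx_val, rows[seq_len(val_alloc[i])])
      idx_te <- c(idx_te, rows[-seq_len(val_alloc[i])])
    }
  } else {
    perm <- sample.int(n)
    idx_tr <- perm[seq_len(n_train)]
    idx_val <- perm[n_train + seq_len(n_val)]
    idx_te <- perm[(n_train + n_val + 1):n]
  }
  sub <- function(idx) feature_table(table$values[idx, , drop = FALSE],
                                     table$labels[idx], table$column_names)
  list(train = sub(idx_tr), val = sub(idx_val), test = sub(idx_te),
       indices = list(train = idx_tr, val = idx_val, test = idx_te))
}

#' Segment a signal into fixed-length overlapping windows
#'
#' Windows of `window_samples` starting at 0, `step_samples`, 2 steps, ...
#' (half-open sample intervals); an incomplete tail is dropped, giving
#' `floor((N - W) / S) + 1` windows.
#'
#' @param sequence numeric vector of length >= `window_samples`.
#' @param window_samples window length W (positive integer).
#' @param step_samples step S, with `1 <= S <= W`.
#' @return matrix, one window per row.
#' @export
segment_signal <- function(sequence, window_samples, step_samples) {
  if (step_samples < 1 || step_samples > window_samples)
    stopf("need 1 <= step_samples <= window_samples")
  n <- length(sequence)
  if (n < window_samples)
    stopf("sequence (%d) shorter than one window (%d)", n, window_samples)
  n_win <- floor((n - window_samples) / step_samples) + 1
  starts <- (seq_len(n_win) - 1) * step_samples
  out <- matrix(0, n_win, window_samples)
  for (i in seq_len(n_win)) out[i, ] <- sequence[starts[i] + seq_len(window_samples)]
  out
}

#' Replicate a trial's labels across its windows
#'
#' Every window inherits its parent trial's VAD label triple; provenance
#' (subject and trial id) is retained per row.
#'
#' @param trial_labels length-3 numeric (valence, arousal, dominance).
#' @param n_windows number of windows (>= 0).
#' @param subject_id,trial_id provenance carried into the output.
#' @return data.frame with columns subject_id, trial_id, valence, arousal,
#'   dominance; one row per window.
#' @export
inherit_labels <- function(trial_labels, n_windows, subject_id = NA_character_,
                           trial_id = NA_integer_) {
  if (n_windows < 0) stopf("n_windows must be >= 0")
  data.frame(subject_id = rep(subject_id, n_windows),
             trial_id = rep(trial_id, n_windows),
             valence = rep(trial_labels[1], n_windows),
             arousal = rep(trial_labels[2], n_windows),
             dominance = rep(trial_labels[3], n_windows))
}

#' Zero-phase Butterworth band-pass or notch filtering
#'
#' Applies the filter forward and backward ([signal::filtfilt()]) per channel,
#' preserving shape and phase. The band-pass is a Butterworth design
#' ([signal::butter()]); the notch is a constrained second-order (biquad)
#' design with centre frequency and quality factor Q.
#'
#' @param record a [signal_record].
#' @param kind `"butterworth_bandpass"` or `"notch"`.
#' @param order Butterworth order (default 4; band-pass only).
#' @param band_hz length-2 band edges in Hz (band-pass only).
#' @param center_hz notch centre frequency in Hz.
#' @param Q notch quality factor (default 30).
#' @return a filtered [signal_record] of identical shape.
#' @export
apply_filter <- function(record, kind = c("butterworth_bandpass", "notch"),
                         order = 4, band_hz = NULL, center_hz = NULL, Q = 30) {
  kind <- match.arg(kind)
  nyq <- record$rate_hz / 2
  if (kind == "butterworth_bandpass") {
    if (is.null(band_hz) || length(band_hz) != 2) stopf("band_hz must be length 2")
    if (any(band_hz <= 0) || any(band_hz >= nyq))
      stopf("band (%g, %g) must lie strictly inside (0, Nyquist = %g)",
            band_hz[1], band_hz[2], nyq)
    flt <- signal::butter(order, band_hz / nyq, type = "pass")
    b <- flt$b; a <- flt$a
  } else {
    if (is.null(center_hz)) stopf("center_hz required for a notch filter")
    if (center_hz <= 0 || center_hz >= nyq)
      stopf("notch centre %g must lie strictly inside (0, Nyquist = %g)", center_hz, nyq)
    w0 <- 2 * pi * center_hz / record$rate_hz
    alpha <- sin(w0) / (2 * Q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    b <- b / a[1]; a <- a / a[1]
  }
  out <- record
  for (i in seq_len(nrow(record$data)))
    out$data[i, ] <- signal::filtfilt(b, a, record$data[i, ])
  out
}

#' Normalize a raw SAM triple from the 1-5 scale to [0, 1]
#'
#' `(x - 1) / 4` per component. Inverse of [denormalize_vad()].
#'
#' @param raw numeric vector (or matrix, by element) with values in `[1, 5]`.
#' @return values mapped to `[0, 1]`.
#' @export
normalize_vad <- function(raw) {
  if (any(raw < 1) || any(raw > 5)) stopf("raw VAD values must lie in [1, 5]")
  (raw - 1) / 4
}

#' Map normalized VAD values back to the 1-5 SAM scale
#'
#' @param x numeric values in `[0, 1]`.
#' @return `x * 4 + 1`.
#' @export
denormalize_vad <- function(x) x * 4 + 1
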
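#' @keywords internal
#' @useDynLib affectkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Rounding convention used everywhere a printed 2-decimal value is compared:
# half away from zero (0.2128 -> 0.21, 0.5346 -> 0.54, -0.125 -> -0.13 at 2 dp).

#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), ties are rounded away from zero,
#' matching the convention of the printed diagnostic tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# population standard deviation (divide by n), the standard-scaler convention
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_prob_triple <- function(p, what = "proportions") {
  if (abs(sum(p) - 1) > 1e-9) stopf("%s must sum to 1 (got %.12f)", what, sum(p))
  invisible(p)
}

# Allocate integer counts for class proportions: round half away from zero,
# then give any remainder to the largest class (deterministic).
allocate_counts <- function(n, proportions) {
  counts <- round_half_away(proportions * n)
  delta <- n - sum(counts)
  if (delta != 0) {
    i <- which.max(proportions)
    counts[i] <- counts[i] + delta
  }
  as.integer(counts)
}

#' Construct a multichannel signal record
#'
#' Container for a sampled multichannel signal: a channels-by-samples matrix,
#' channel names, one sampling rate and a start offset in seconds.
#'
#' @param data numeric matrix, channels x samples.
#' @param rate_hz sampling rate in Hz, > 0.
#' @param channel_names character vector, one per row of `data`.
#' @param start_offset_s recording start offset in seconds.
#' @return an object of class `signal_record`.
#' @export
signal_record <- function(data, rate_hz, channel_names = NULL, start_offset_s = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stopf("channel_names length (%d) must equal number of data rows (%d)",
          length(channel_names), nrow(data))
  if (!is.numeric(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  structure(list(channel_names = as.character(channel_names),
                 data = data, rate_hz = rate_hz,
                 start_offset_s = start_offset_s),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz, ncol(x$data) / x$rate_hz))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a trial set
#'
#' A flat collection of per-subject, per-trial ECG sequences with raw
#' self-assessment (SAM) valence/arousal/dominance ratings on the 1-5 scale.
#'
#' @param trials list; each element a list with fields `subject_id` (character),
#'   `trial_id` (integer), `ecg` (numeric vector), and `vad_raw` (length-3
#'   numeric, ordered valence, arousal, dominance, each in `[1, 5]`).
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(trials) {
  for (tr in trials) {
    if (length(tr$ecg) < 1) stopf("trial %s/%s has empty ecg", tr$subject_id, tr$trial_id)
    if (length(tr$vad_raw) != 3 || any(tr$vad_raw < 1) || any(tr$vad_raw > 5))
      stopf("trial %s/%s: vad_raw must be 3 values in [1, 5]", tr$subject_id, tr$trial_id)
  }
  structure(list(trials = trials), class = "trial_set")
}

#' @export
length.trial_set <- function(x) length(x$trials)

#' @export
print.trial_set <- function(x, ...) {
  ns <- length(unique(vapply(x$trials, function(t) t$subject_id, "")))
  cat(sprintf("<trial_set> %d trials from %d subject(s)\n", length(x$trials), ns))
  invisible(x)
}

#' Construct a labeled feature table
#'
#' Rows-by-features numeric matrix with column names and one integer label per
#' row; the tabular container consumed by the stress-classification path.
#'
#' @param values numeric matrix (rows x features).
#' @param labels integer vector, one per row.
#' @param column_names character vector, one per column.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, labels, column_names = colnames(values)) {
  if (!is.matrix(values)) stopf("values must be a matrix")
  if (is.null(column_names)) column_names <- paste0("f", seq_len(ncol(values)))
  if (length(column_names) != ncol(values))
    stopf("column_names length (%d) != column count (%d)", length(column_names), ncol(values))
  if (length(labels) != nrow(values))
    stopf("labels length (%d) != row count (%d)", length(labels), nrow(values))
  colnames(values) <- column_names
  structure(list(column_names = as.character(column_names),
                 values = values, labels = as.integer(labels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d rows x %d features; label counts:\n",
              nrow(x$values), ncol(x$values)))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)
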
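# Evaluation metrics: confusion matrix, per-class/macro/weighted
# classification report, and the regression report (MAE, RMSE, R-squared,
# Smooth-L1, rounded accuracy per dimension and across all dimensions).

#' Confusion matrix of 0-based labels
#'
#' Entry (i, j) counts samples with true class i predicted as class j; row
#' sums are the class supports.
#'
#' @param y_true,y_pred integer vectors with values in `{0, ..., k-1}`.
#' @param k number of classes (default `max(labels) + 1`).
#' @return k x k integer matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, k = NULL) {
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  if (is.null(k)) k <- max(c(y_true, y_pred)) + 1L
  if (any(y_true < 0 | y_true >= k) || any(y_pred < 0 | y_pred >= k))
    stopf("labels out of range [0, %d]", k - 1)
  m <- matrix(0L, k, k, dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
  for (i in seq_along(y_true))
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  m
}

#' Classification report from a confusion matrix
#'
#' Per-class precision (`diag / column sum`, 0 with a warning for an empty
#' predicted class), recall (`diag / row sum`), F1 (harmonic mean), support;
#' overall accuracy (`trace / n`); macro (unweighted) and support-weighted
#' averages. The weighted recall equals the accuracy by construction.
#'
#' @param confusion k x k count matrix from [confusion_matrix()].
#' @return list of class `classification_report` with `per_class`
#'   (data.frame), `accuracy`, `macro` and `weighted` rows.
#' @export
classification_report <- function(confusion) {
  m <- as.matrix(confusion)
  if (length(m) == 0 || sum(m) == 0) stopf("empty confusion matrix")
  k <- nrow(m)
  support <- rowSums(m)
  predicted <- colSums(m)
  precision <- numeric(k); recall <- numeric(k)
  for (c in seq_len(k)) {
    if (predicted[c] == 0) {
      warnf("class %d never predicted; precision set to 0", c - 1)
      precision[c] <- 0
    } else precision[c] <- m[c, c] / predicted[c]
    recall[c] <- if (support[c] == 0) 0 else m[c, c] / support[c]
  }
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  n <- sum(m)
  acc <- sum(diag(m)) / n
  w <- support / n
  res <- list(
    per_class = data.frame(class = 0:(k - 1), precision = precision,
                           recall = recall, f1 = f1, support = support,
                           row.names = NULL),
    accuracy = acc,
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    n = n)
  class(res) <- "classification_report"
  res
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  fmt <- function(v) formatC(round_half_away(v, digits), format = "f", digits = digits)
  cat("Class  Precision  Recall  F1-score  Support\n")
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("%-6s %9s %7s %9s %8d\n", x$per_class$class[i],
                fmt(x$per_class$precision[i]), fmt(x$per_class$recall[i]),
                fmt(x$per_class$f1[i]), x$per_class$support[i]))
  cat(sprintf("Accuracy %30s %8d\n", fmt(x$accuracy), x$n))
  cat(sprintf("Macro Avg %8s %7s %9s %8d\n", fmt(x$macro["precision"]),
              fmt(x$macro["recall"]), fmt(x$macro["f1"]), x$n))
  cat(sprintf("Weighted Avg %5s %7s %9s %8d\n", fmt(x$weighted["precision"]),
              fmt(x$weighted["recall"]), fmt(x$weighted["f1"]), x$n))
  invisible(x)
}

#' Regression metrics for VAD prediction
#'
#' MAE and RMSE pooled over all n x d entries; R-squared computed per
#' dimension and averaged (the pooled variant is also returned); Smooth-L1
#' with `beta = 1`; and rounded accuracy: predictions and targets are mapped
#' back to the 1-5 scale (`x * 4 + 1`), rounded half away from zero to
#' integers, and compared -- per dimension, and jointly (a sample counts for
#' the all-dimensions accuracy only if every dimension matches, so the joint
#' value never exceeds any per-dimension value). Accuracies are percentages.
#'
#' @param pred,truth numeric matrices (n x d) on the normalized `[0,1]` scale.
#' @return list of class `regression_report`: `mae`, `rmse`, `r2`
#'   (per-dimension average), `r2_per_dim`, `r2_pooled`, `smooth_l1`,
#'   `rounded_accuracy_all`, `rounded_accuracy_per_dim`.
#' @export
regression_metrics <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stopf("pred and truth shapes differ")
  e <- pred - truth
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  sstot <- vapply(seq_len(ncol(truth)), function(j)
    sum((truth[, j] - mean(truth[, j]))^2), 0)
  if (any(sstot == 0))
    stopf("R-squared undefined: constant target dimension(s) %s",
          paste(which(sstot == 0), collapse = ", "))
  r2_dim <- vapply(seq_len(ncol(truth)), function(j)
    1 - sum((truth[, j] - pred[, j])^2) / sstot[j], 0)
  r2_pooled <- 1 - sum(e^2) / sum((truth - mean(truth))^2)
  ip <- round_half_away(denormalize_vad(pred))
  it <- round_half_away(denormalize_vad(truth))
  match_dim <- ip == it
  per_dim <- 100 * colMeans(match_dim)
  all_dims <- 100 * mean(rowSums(match_dim) == ncol(truth))
  res <- list(mae = mae, rmse = rmse, r2 = mean(r2_dim), r2_per_dim = r2_dim,
              r2_pooled = r2_pooled, smooth_l1 = smooth_l1(pred, truth),
              rounded_accuracy_all = all_dims,
              rounded_accuracy_per_dim = per_dim)
  class(res) <- "regression_report"
  res
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Mean Absolute Error (MAE)        %.4f\n", x$mae))
  cat(sprintf("Root mean square error (RMSE)    %.4f\n", x$rmse))
  cat(sprintf("R^2 Score                        %.4f\n", x$r2))
  cat(sprintf("Rounded Accuracy (All Dimensions) %.2f%%\n", x$rounded_accuracy_all))
  for (j in seq_along(x$rounded_accuracy_per_dim))
    cat(sprintf("Accuracy: Dimension %d            %.2f%%\n", j,
                x$rounded_accuracy_per_dim[j]))
  invisible(x)
}
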
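# Attribution and embedding visualization: 1D Grad-CAM (single- and
# multi-channel), Integrated Gradients with a completeness report, attention
# extraction from the conformer encoder, and an exact t-SNE projection of
# pooled embeddings. Every method returns plain arrays so properties are
# testable without rendering.

# gradient of one class logit wrt the output of layer `layer_name`
# and wrt the model input. Inference mode (running BN stats, no dropout).
.class_gradients <- function(model, x, target_class, layer_name = NULL) {
  fw <- nn_forward(model, x, training = FALSE)
  n_out <- ncol(fw$out)
  if (target_class < 0 || target_class >= n_out)
    stopf("class index %d out of range [0, %d]", target_class, n_out - 1)
  dout <- matrix(0, nrow(fw$out), n_out)
  dout[, target_class + 1] <- 1
  bk <- nn_backward(model, fw$caches, dout)
  li <- if (!is.null(layer_name)) {
    idx <- which(vapply(model$layers, function(l) l$name, "") == layer_name)
    if (!length(idx)) stopf("no layer named '%s'", layer_name)
    idx
  } else NULL
  # gradient wrt layer i's output = gradient wrt layer (i+1)'s input
  d_layer_out <- if (!is.null(li)) {
    if (li < length(model$layers)) bk$layer_dx[[li + 1]] else dout
  } else NULL
  acts <- if (!is.null(li)) {
    a <- .as_btc(x)
    for (j in seq_len(li)) a <- .layer_forward(model$layers[[j]], a, FALSE)$out
    a
  } else NULL
  list(forward = fw, d_input = bk$dx, d_layer_out = d_layer_out,
       activations = acts, logits = fw$out)
}

# linear interpolation of a vector onto `n_out` points
.upsample_linear <- function(v, n_out) {
  if (length(v) == n_out) return(v)
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = n_out))$y
}

#' 1D Grad-CAM heatmap for a convolutional classifier
#'
#' Backpropagates the target-class logit to the chosen convolutional layer,
#' weights each filter's activation map by the time-averaged gradient,
#' rectifies the weighted sum, linearly upsamples it to the input length and
#' min-max normalizes to `[0, 1]`. A map that is all zero after the ReLU
#' (a flat response) is returned as zeros rather than an error.
#'
#' @param model a trained `affect_nn` classifier.
#' @param input single input: numeric vector (single channel) or T x C matrix.
#' @param target_class 0-based class index.
#' @param conv_layer name of a conv layer (default `"conv2"`, the final one).
#' @return list with `values` (heatmap in `[0,1]`, length = input length),
#'   `target_class` and `layer_name`.
#' @export
grad_cam_1d <- function(model, input, target_class, conv_layer = "conv2") {
  x <- if (is.matrix(input)) array(input, c(1, dim(input))) else
    matrix(input, 1, length(input))
  li <- which(vapply(model$layers, function(l) l$name, "") == conv_layer)
  if (!length(li)) stopf("no layer named '%s'", conv_layer)
  if (model$layers[[li]]$type != "conv1d")
    stopf("layer '%s' is not convolutional", conv_layer)
  g <- .class_gradients(model, x, target_class, conv_layer)
  da <- dim(g$activations)
  A <- matrix(g$activations[1, , ], da[2], da[3])  # T\' x filters
  dA <- matrix(g$d_layer_out[1, , ], da[2], da[3])
  w <- colMeans(dA)                               # per-filter weight
  cam <- pmax(as.vector(A %*% w), 0)
  input_len <- if (is.matrix(input)) nrow(input) else length(input)
  cam <- .upsample_linear(cam, input_len)
  mx <- max(cam)
  values <- if (mx > 0) cam / mx else cam * 0
  list(values = values, target_class = target_class, layer_name = conv_layer)
}

#' Multichannel Grad-CAM
#'
#' Per-channel heatmaps aligned to the time axis: the Grad-CAM time profile
#' from the final convolutional layer is distributed across input channels
#' in proportion to each channel's mean absolute input gradient for the
#' target class, then the channel maps are normalized jointly (global max 1)
#' or per channel. With a single input channel this reduces exactly to
#' [grad_cam_1d()].
#'
#' @param model a trained `affect_nn` classifier.
#' @param input T x C matrix (or vector for one channel).
#' @param target_class 0-based class index.
#' @param conv_layer conv layer name (default `"conv2"`).
#' @param normalize `"joint"` (default) or `"per_channel"`.
#' @return list with `values` (C x T matrix in `[0,1]`), `channel_relevance`,
#'   `target_class`, `layer_name`.
#' @export
grad_cam_multichannel <- function(model, input, target_class,
                                  conv_layer = "conv2",
                                  normalize = c("joint", "per_channel")) {
  normalize <- match.arg(normalize)
  if (!is.matrix(input)) input <- matrix(input, ncol = 1)
  cam <- grad_cam_1d(model, input, target_class, conv_layer)
  x <- array(input, c(1, dim(input)))
  g <- .class_gradients(model, x, target_class)
  dinp <- array(g$d_input, dim(input))            # T x C
  rel <- colMeans(abs(dinp))
  rel <- if (max(rel) > 0) rel / max(rel) else rel
  maps <- outer(rel, cam$values)                  # C x T
  if (normalize == "joint") {
    mx <- max(maps)
    if (mx > 0) maps <- maps / mx
  } else {
    for (c in seq_len(nrow(maps))) {
      mx <- max(maps[c, ])
      if (mx > 0) maps[c, ] <- maps[c, ] / mx
    }
  }
  list(values = maps, channel_relevance = rel,
       target_class = target_class, layer_name = cam$layer_name)
}

#' Integrated Gradients attribution
#'
#' Path attribution from a baseline to the input: the input-minus-baseline
#' difference times the average input gradient over a midpoint Riemann grid
#' of `steps` interpolants. The completeness gap
#' `sum(IG) - (F(x) - F(baseline))` is reported; it shrinks as `steps` grows.
#'
#' @param model a trained `affect_nn` model.
#' @param input numeric vector (single-channel input).
#' @param target 0-based output index to attribute.
#' @param baseline baseline input (default zeros, in the model's normalized
#'   input space).
#' @param steps Riemann grid size (default 50).
#' @return list with `attributions` (signed, same length as input),
#'   `completeness_gap`, `baseline`, `steps`.
#' @export
integrated_gradients <- function(model, input, target, baseline = NULL,
                                 steps = 50) {
  x <- as.numeric(input)
  b <- if (is.null(baseline)) numeric(length(x)) else as.numeric(baseline)
  if (length(b) != length(x)) stopf("baseline length must match input")
  alphas <- (seq_len(steps) - 0.5) / steps
  interp <- matrix(rep(b, each = steps), steps, length(x)) +
    outer(alphas, x - b)
  g <- .class_gradients(model, interp, target)
  avg_grad <- colMeans(matrix(g$d_input, steps, length(x)))
  attributions <- (x - b) * avg_grad
  fx <- .class_gradients(model, matrix(x, 1), target)$logits[1, target + 1]
  fb <- .class_gradients(model, matrix(b, 1), target)$logits[1, target + 1]
  list(attributions = attributions,
       completeness_gap = sum(attributions) - (fx - fb),
       baseline = b, steps = steps)
}

#' Extract attention maps from a conformer
#'
#' Runs the model in inference mode and returns the self-attention
#' probabilities of every encoder layer. Rows are softmax distributions over
#' key positions and sum to 1.
#'
#' @param model an `affect_nn` model built by [build_conformer()].
#' @param input single feature vector (length `input_len`) or an n x len
#'   matrix (attention is returned for the first sample).
#' @return array (layers x heads x T x T).
#' @export
extract_attention <- function(model, input) {
  x <- if (is.matrix(input)) input[1, , drop = FALSE] else matrix(input, 1)
  fw <- nn_forward(model, x, training = FALSE)
  enc <- which(vapply(model$layers, function(l) l$type, "") == "encoder")
  if (!length(enc)) stopf("model has no attention-capturing encoder layers")
  T_ <- dim(fw$caches[[enc[1]]]$attention)[3]
  h <- dim(fw$caches[[enc[1]]]$attention)[2]
  out <- array(0, c(length(enc), h, T_, T_))
  for (i in seq_along(enc))
    out[i, , , ] <- fw$caches[[enc[i]]]$attention[1, , , ]
  out
}

#' Exact t-SNE embedding
#'
#' Standard t-SNE (exact pairwise affinities, perplexity calibrated per point
#' by bisection, early exaggeration, momentum gradient descent) projecting
#' features -- typically the global-average-pooling embeddings of the
#' classifier -- to two dimensions. Deterministic under `seed`.
#'
#' @param features numeric matrix (n x d), with `n > 3 * perplexity`.
#' @param perplexity neighborhood size parameter (default 30).
#' @param seed RNG seed for the initial layout.
#' @param n_iter gradient-descent iterations (default 400).
#' @param learning_rate step size (default 100).
#' @return n x 2 coordinate matrix.
#' @export
tsne_embed <- function(features, perplexity = 30, seed = 1, n_iter = 400,
                       learning_rate = 100) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stopf("need n > 3 * perplexity (n = %d, perplexity = %g)", n, perplexity)
  D2 <- as.matrix(stats::dist(X))^2
  target_entropy <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- 0; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - target_entropy) < 1e-5) break
      if (H > target_entropy) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
  vel <- matrix(0, n, 2)
  exaggeration <- 4; stop_exag <- floor(n_iter / 4)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= stop_exag) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it < 100) 0.5 else 0.8
    vel <- momentum * vel - learning_rate * grad
    Y <- Y + vel
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
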
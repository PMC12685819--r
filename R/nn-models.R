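# Model builders and training loops: the 1D-CNN stress classifier, its
# transfer-learning fine-tuning, and the Temporal Conformer VAD regressor.

#' Build the 1D-CNN classifier
#'
#' Layer order: Conv1D(64, k=3, ReLU, L2) -> BatchNorm -> MaxPool(2) ->
#' Dropout -> Conv1D(128, k=3, ReLU, L2) -> BatchNorm -> MaxPool(2) ->
#' Dropout -> GlobalAvgPool -> Dense(64, ReLU) -> Dropout -> Dense(n_classes)
#' with softmax applied at prediction/loss time. Convolutions use same
#' padding; a feature row is consumed as a length-`input_len` 1-channel
#' sequence.
#'
#' @param input_len input sequence length (>= 4, so two pools fit).
#' @param n_classes number of output classes (>= 2).
#' @param input_channels input channels (default 1).
#' @param filters1,filters2 conv filters (defaults 64 and 128).
#' @param kernel conv kernel size (odd; default 3).
#' @param pool_size max-pool size (default 2).
#' @param dropout dropout rate (default 0.4).
#' @param l2_coeff L2 penalty coefficient on conv/dense kernels (default 1e-4).
#' @param dense_units dense layer width (default 64).
#' @param seed seed for weight initialization.
#' @return an `affect_nn` model.
#' @export
build_cnn <- function(input_len, n_classes, input_channels = 1,
                      filters1 = 64, filters2 = 128, kernel = 3,
                      pool_size = 2, dropout = 0.4, l2_coeff = 1e-4,
                      dense_units = 64, seed = 1) {
  if (n_classes < 2) stopf("n_classes must be >= 2")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (floor(floor(input_len / pool_size) / pool_size) < 1)
    stopf("input_len %d too short for two pooling stages", input_len)
  set.seed(seed)
  layers <- list(
    layer_conv1d("conv1", input_channels, filters1, kernel, "relu", l2_coeff),
    layer_batchnorm("bn1", filters1),
    layer_maxpool("pool1", pool_size),
    layer_dropout("drop1", dropout),
    layer_conv1d("conv2", filters1, filters2, kernel, "relu", l2_coeff),
    layer_batchnorm("bn2", filters2),
    layer_maxpool("pool2", pool_size),
    layer_dropout("drop2", dropout),
    layer_gap("gap"),
    layer_dense("dense", filters2, dense_units, "relu", l2_coeff),
    layer_dropout("drop3", dropout),
    layer_dense("head", dense_units, n_classes, "linear", l2_coeff))
  structure(list(layers = layers, kind = "cnn1d", input_len = input_len,
                 input_channels = input_channels, n_classes = n_classes),
            class = "affect_nn")
}

#' Build the Temporal Conformer VAD regressor
#'
#' Conv stack (32 then 64 filters, ReLU + dropout, same padding over the
#' 33-step feature sequence) -> position-wise dense projection -> `n_layers`
#' post-norm transformer encoder blocks (multi-head self-attention with
#' retrievable attention weights, residuals, layer norm, dropout) -> final
#' layer norm -> dropout -> flatten -> Dense(3).
#'
#' @param input_len input sequence length (default 33, the feature vector as
#'   a 1-channel sequence).
#' @param conv_filters two conv widths (default c(32, 64)).
#' @param projection_dim encoder width d (default 64, divisible by `n_heads`).
#' @param n_layers number of encoder blocks (default 2).
#' @param n_heads attention heads (default 4).
#' @param ff_dim encoder feed-forward width (default 128).
#' @param dropout dropout rate (default 0.1).
#' @param output_dim output dimension (3: valence, arousal, dominance).
#' @param seed seed for weight initialization.
#' @return an `affect_nn` model.
#' @export
build_conformer <- function(input_len = 33, conv_filters = c(32, 64),
                            projection_dim = 64, n_layers = 2, n_heads = 4,
                            ff_dim = 128, dropout = 0.1, output_dim = 3,
                            seed = 1) {
  if (projection_dim %% n_heads != 0)
    stopf("projection_dim must be divisible by n_heads")
  set.seed(seed)
  layers <- list(
    layer_conv1d("conv1", 1, conv_filters[1], 3, "relu"),
    layer_dropout("drop1", dropout),
    layer_conv1d("conv2", conv_filters[1], conv_filters[2], 3, "relu"),
    layer_dropout("drop2", dropout),
    layer_timedense("proj", conv_filters[2], projection_dim, "linear"))
  for (l in seq_len(n_layers))
    layers <- c(layers, list(layer_encoder(sprintf("enc%d", l), projection_dim,
                                           n_heads, ff_dim, dropout)))
  layers <- c(layers, list(
    layer_layernorm("norm_final", projection_dim),
    layer_dropout("drop_final", dropout),
    layer_flatten("flatten"),
    layer_dense("head", input_len * projection_dim, output_dim, "linear")))
  structure(list(layers = layers, kind = "conformer", input_len = input_len,
                 input_channels = 1, n_classes = output_dim),
            class = "affect_nn")
}

#' @export
print.affect_nn <- function(x, ...) {
  cat(sprintf("<affect_nn:%s> %d layers, %d parameters, input length %d\n",
              x$kind, length(x$layers), nn_param_count(x), x$input_len))
  invisible(x)
}

#' Balanced per-class weights
#'
#' `w_c = n / (k * n_c)` so that `sum_c n_c w_c = n`; balanced counts give
#' unit weights.
#'
#' @param labels 0-based integer class labels; every class `0..max(labels)`
#'   must be present.
#' @return numeric vector of length k (class 0 first).
#' @export
compute_class_weights <- function(labels) {
  k <- max(labels) + 1L
  counts <- tabulate(labels + 1L, k)
  if (any(counts == 0))
    stopf("empty class(es): %s", paste(which(counts == 0) - 1, collapse = ", "))
  sum(counts) / (k * counts)
}

#' Training configuration
#'
#' @param lr initial learning rate (classifier pretraining default 1e-3;
#'   fine-tuning uses 1e-4).
#' @param batch_size minibatch size (default 128).
#' @param max_epochs epoch cap (default 50).
#' @param early_stop_patience epochs without val-loss improvement before
#'   stopping (best weights restored; default 8).
#' @param plateau_patience epochs without improvement before the learning
#'   rate is multiplied by `plateau_factor` (default 4).
#' @param plateau_factor multiplicative decay (default 0.5).
#' @param min_lr learning-rate floor (default 1e-6).
#' @param loss `"ce"` (sparse cross-entropy) or `"focal"`.
#' @param gamma focal-loss exponent (default 2).
#' @param class_weights optional per-class weights (`"balanced"` to compute
#'   them from the training labels, or a numeric vector, or NULL).
#' @param seed RNG seed controlling shuffling, dropout and any head init.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 128, max_epochs = 50,
                         early_stop_patience = 8, plateau_patience = 4,
                         plateau_factor = 0.5, min_lr = 1e-6,
                         loss = c("ce", "focal"), gamma = 2,
                         class_weights = NULL, seed = 1) {
  if (lr <= 0) stopf("lr must be > 0")
  if (plateau_factor <= 0 || plateau_factor >= 1) stopf("plateau factor must be in (0,1)")
  structure(list(lr = lr, batch_size = batch_size, max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 plateau_patience = plateau_patience,
                 plateau_factor = plateau_factor, min_lr = min_lr,
                 loss = match.arg(loss), gamma = gamma,
                 class_weights = class_weights, seed = seed),
            class = "train_config")
}

#' Learning-rate trace of the reduce-on-plateau schedule
#'
#' Pure helper exposing the scheduler contract: given a stream of validation
#' losses, returns the learning rate in effect at each epoch. The rate is
#' multiplied by `factor` after `patience` consecutive epochs without
#' improvement and floored at `min_lr`; the sequence is non-increasing.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param lr0 initial rate.
#' @param factor decay factor in (0, 1).
#' @param patience epochs without improvement before a reduction.
#' @param min_lr floor.
#' @return numeric vector, `lr` at each epoch.
#' @export
plateau_schedule <- function(val_losses, lr0 = 1e-3, factor = 0.5,
                             patience = 1, min_lr = 1e-6) {
  lr <- lr0; best <- Inf; wait <- 0
  out <- numeric(length(val_losses))
  for (i in seq_along(val_losses)) {
    out[i] <- lr
    if (val_losses[i] < best - 1e-12) { best <- val_losses[i]; wait <- 0 }
    else {
      wait <- wait + 1
      if (wait >= patience) { lr <- max(min_lr, lr * factor); wait <- 0 }
    }
  }
  out
}

# generic minibatch trainer shared by the classifier and the regressor.
# task = "classify": y 0-based ints; task = "regress": y numeric matrix.
.train_network <- function(model, x, y, x_val, y_val, config,
                           task = c("classify", "regress"),
                           frozen_layers = character(0), verbose = FALSE) {
  task <- match.arg(task)
  set.seed(config$seed)
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  cw <- config$class_weights
  if (identical(cw, "balanced")) cw <- compute_class_weights(y)
  opt <- .adam_init(model)
  lr <- config$lr
  best_val <- Inf; best_snap <- .nn_snapshot(model)
  es_wait <- 0; pl_wait <- 0
  hist <- list()
  take <- function(xx, idx) {
    if (is.matrix(xx)) xx[idx, , drop = FALSE] else xx[idx, , , drop = FALSE]
  }
  eval_loss <- function(m, xx, yy) {
    fw <- nn_forward(m, xx, training = FALSE)
    if (task == "classify") {
      r <- .clf_loss_grad(fw$out, yy, NULL, config$loss, config$gamma, want_grad = FALSE)
      list(loss = r$loss, metric = mean(max.col(r$probs) - 1L == yy))
    } else {
      list(loss = smooth_l1(fw$out, yy), metric = mean(.r2_per_dim(fw$out, yy)))
    }
  }
  for (epoch in seq_len(max(config$max_epochs, 0))) {
    perm <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      xb <- take(x, idx)
      fw <- nn_forward(model, xb, training = TRUE)
      model <- fw$model
      if (task == "classify") {
        lg <- .clf_loss_grad(fw$out, y[idx], cw, config$loss, config$gamma)
        loss <- lg$loss; dout <- lg$grad
      } else {
        yb <- y[idx, , drop = FALSE]
        loss <- smooth_l1(fw$out, yb)
        dout <- .smooth_l1_grad(fw$out, yb)
      }
      loss <- loss + .l2_penalty(model)
      if (!is.finite(loss))
        stopf("non-finite training loss at epoch %d; reduce the learning rate", epoch)
      bk <- nn_backward(model, fw$caches, dout)
      if (length(frozen_layers))
        for (i in seq_along(model$layers))
          if (model$layers[[i]]$name %in% frozen_layers) bk$grads[[i]] <- list()
      st <- .adam_step(model, opt, bk$grads, lr)
      model <- st$model; opt <- st$opt
      batch_losses <- c(batch_losses, loss)
    }
    ev <- eval_loss(model, x_val, y_val)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(batch_losses),
                                val_loss = ev$loss, val_metric = ev$metric, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  metric %.4f  lr %g",
                      epoch, mean(batch_losses), ev$loss, ev$metric, lr))
    if (ev$loss < best_val - 1e-12) {
      best_val <- ev$loss; best_snap <- .nn_snapshot(model)
      es_wait <- 0; pl_wait <- 0
    } else {
      es_wait <- es_wait + 1; pl_wait <- pl_wait + 1
      if (pl_wait >= config$plateau_patience) {
        lr <- max(config$min_lr, lr * config$plateau_factor); pl_wait <- 0
      }
      if (es_wait >= config$early_stop_patience) break
    }
  }
  model <- .nn_restore(model, best_snap)
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               val_loss = numeric(0), val_metric = numeric(0), lr = numeric(0))
  list(model = model, history = history)
}

#' Train a classifier with early stopping and plateau scheduling
#'
#' Minibatch Adam with optional class weighting (weights multiply each
#' sample's loss), sparse cross-entropy or focal loss, early stopping that
#' restores the best-validation-loss weights, and reduce-on-plateau learning
#' rate decay. Fully seeded: two runs with the same seed are identical.
#'
#' @param model an `affect_nn` classifier (see [build_cnn()]).
#' @param x_train,y_train training inputs (matrix rows = samples) and 0-based
#'   labels.
#' @param x_val,y_val validation data monitored for scheduling/stopping.
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history` (per-epoch train/val loss,
#'   validation accuracy and learning rate).
#' @export
train_classifier <- function(model, x_train, y_train, x_val, y_val,
                             config = train_config(), verbose = FALSE) {
  .train_network(model, x_train, y_train, x_val, y_val, config,
                 task = "classify", verbose = verbose)
}

#' Train the VAD regressor with Smooth-L1 loss
#'
#' Same trainer as [train_classifier()] but with the Smooth-L1 (Huber)
#' objective and mean per-dimension R-squared as the monitored metric.
#' Targets must be normalized VAD triples in `[0, 1]`.
#'
#' @param model an `affect_nn` regressor (see [build_conformer()]).
#' @param x_train,y_train features (n x 33) and targets (n x 3 in `[0,1]`).
#' @param x_val,y_val validation split.
#' @param config a [train_config()] (use a larger `max_epochs`, e.g. 100).
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history`.
#' @export
train_vad_regressor <- function(model, x_train, y_train, x_val, y_val,
                                config = train_config(max_epochs = 100),
                                verbose = FALSE) {
  if (any(y_train < 0) || any(y_train > 1))
    stopf("targets must be normalized to [0, 1]; see normalize_vad()")
  .train_network(model, x_train, y_train, x_val, y_val, config,
                 task = "regress", verbose = verbose)
}

#' Class probabilities and hard labels from a classifier
#'
#' @param model a trained `affect_nn` classifier.
#' @param x input matrix/array.
#' @return list with `probs` (rows sum to 1) and `labels` (0-based).
#' @export
predict_classes <- function(model, x) {
  probs <- softmax(nn_forward(model, x, training = FALSE)$out)
  list(probs = probs, labels = max.col(probs) - 1L)
}

#' Predicted VAD triples from a regressor
#'
#' @param model a trained `affect_nn` regressor.
#' @param x feature matrix (n x input_len).
#' @return n x 3 matrix (valence, arousal, dominance).
#' @export
predict_vad <- function(model, x) {
  out <- nn_forward(model, x, training = FALSE)$out
  colnames(out) <- c("valence", "arousal", "dominance")
  out
}

#' Activation of a named layer
#'
#' Runs the model in inference mode and returns the output of the layer with
#' the given name (e.g. `"gap"` for the pooled embedding fed to t-SNE).
#'
#' @param model an `affect_nn` model.
#' @param x input batch.
#' @param layer_name layer name.
#' @return that layer's output (matrix or array).
#' @export
nn_activation <- function(model, x, layer_name) {
  a <- .as_btc(x)
  for (l in model$layers) {
    step <- .layer_forward(l, a, training = FALSE)
    a <- step$out
    if (l$name == layer_name) return(a)
  }
  stopf("no layer named '%s'", layer_name)
}

# ---- checkpoints ------------------------------------------------------------

.model_architecture <- function(model) {
  lapply(model$layers, function(l) {
    shapes <- lapply(l$params, function(p) {
      d <- dim(p); if (is.null(d)) length(p) else d
    })
    cfg <- l[setdiff(names(l), c("params", "running_mean", "running_var",
                                 "type", "name"))]
    list(name = l$name, kind = l$type, config = cfg, params = shapes)
  })
}

#' Bundle a model into a checkpoint
#'
#' @param model an `affect_nn` model.
#' @param metadata named list stored alongside (dataset tag, epoch, seed...).
#' @return a [checkpoint_bundle].
#' @export
model_to_checkpoint <- function(model, metadata = list()) {
  weights <- list()
  for (l in model$layers)
    for (nm in names(l$params))
      weights[[sprintf("%s.%s", l$name, nm)]] <- l$params[[nm]]
  metadata$kind <- model$kind
  metadata$input_len <- model$input_len
  metadata$n_classes <- model$n_classes
  checkpoint_bundle(.model_architecture(model), weights, metadata)
}

#' Load checkpoint weights into a model
#'
#' Copies every weight whose `layer.param` name exists in the model. Layers
#' named in `skip` keep their current (e.g. freshly seeded) parameters.
#' A shape mismatch on a non-skipped layer is an error.
#'
#' @param model target `affect_nn` model.
#' @param bundle a [checkpoint_bundle].
#' @param skip layer names to leave untouched (e.g. `"head"`).
#' @return the model with loaded weights.
#' @export
load_weights_into <- function(model, bundle, skip = character(0)) {
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$name %in% skip) next
    for (nm in names(l$params)) {
      key <- sprintf("%s.%s", l$name, nm)
      w <- bundle$weights[[key]]
      if (is.null(w)) next
      have <- dim(l$params[[nm]]) %||% length(l$params[[nm]])
      got <- dim(w) %||% length(w)
      if (!identical(as.integer(have), as.integer(got)))
        stopf("incompatible backbone shape for %s: model (%s) vs checkpoint (%s)",
              key, paste(have, collapse = "x"), paste(got, collapse = "x"))
      model$layers[[i]]$params[[nm]] <- w
    }
  }
  model
}

#' Fine-tune a pretrained classifier on a new task
#'
#' Builds a fresh CNN for the new input length and class count, loads every
#' backbone weight from the checkpoint (the output head is rebuilt and
#' seeded), then trains with a reduced learning rate (default 1e-4) and
#' class weighting. Multichannel inputs use the package's flattening
#' convention: a (T x C) window becomes one channel of length T*C.
#'
#' @param pretrained a [checkpoint_bundle] from [model_to_checkpoint()].
#' @param x_train,y_train,x_val,y_val new-task data (labels 0-based).
#' @param n_classes class count of the new task.
#' @param config a [train_config()]; default lr 1e-4, balanced class weights.
#' @param freeze_conv if TRUE the conv/batchnorm blocks are not updated.
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history`.
#' @export
fine_tune <- function(pretrained, x_train, y_train, x_val, y_val, n_classes,
                      config = train_config(lr = 1e-4, class_weights = "balanced"),
                      freeze_conv = FALSE, verbose = FALSE) {
  input_len <- ncol(x_train)
  model <- build_cnn(input_len, n_classes, seed = config$seed)
  model <- load_weights_into(model, pretrained, skip = "head")
  if (config$max_epochs < 1) return(list(model = model, history = NULL))
  frozen <- if (freeze_conv) c("conv1", "bn1", "conv2", "bn2") else character(0)
  .train_network(model, x_train, y_train, x_val, y_val, config,
                 task = "classify", frozen_layers = frozen, verbose = verbose)
}

.r2_per_dim <- function(pred, truth) {
  vapply(seq_len(ncol(truth)), function(j) {
    ssres <- sum((truth[, j] - pred[, j])^2)
    sstot <- sum((truth[, j] - mean(truth[, j]))^2)
    1 - ssres / sstot
  }, 0)
}

#' Flatten multichannel windows to single-channel rows
#'
#' The transfer-learning convention for multichannel activity windows: each
#' (T x C) window becomes a length T*C single-channel sequence with channel
#' blocks concatenated, so the pretrained backbone (whose convolutions are
#' channel-count-dependent) applies unchanged.
#'
#' @param windows array (n x T x C).
#' @return matrix (n x T*C).
#' @export
flatten_windows <- function(windows) {
  d <- dim(windows)
  matrix(windows, d[1], d[2] * d[3])
}
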
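# A small, fully deterministic neural-network engine in base R: 1D
# convolutions (im2col), batch normalization, max pooling, dropout, global
# average pooling, dense and position-wise dense layers, layer normalization
# and a post-norm transformer encoder block with multi-head self-attention.
# Backpropagation is hand-derived per layer and verified against central
# finite differences in the test suite. Sequence activations are arrays of
# dim (batch, time, channels); after flatten/pool they are (batch, units)
# matrices. All randomness goes through R's RNG so a fixed seed reproduces
# training exactly.

# add a length-C vector to each row of an (N x C) matrix without sweep()
.addrow <- function(z, b) z + rep(b, each = nrow(z))

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# ---- layer constructors -----------------------------------------------------

layer_conv1d <- function(name, in_ch, filters, kernel = 3,
                         activation = c("relu", "linear"), l2 = 0) {
  if (kernel %% 2 == 0) stopf("conv kernel must be odd for same padding")
  activation <- match.arg(activation)
  list(type = "conv1d", name = name, in_ch = in_ch, filters = filters,
       kernel = kernel, activation = activation, l2 = l2,
       params = list(W = .he_init(kernel * in_ch, filters, kernel * in_ch),
                     b = numeric(filters)))
}

layer_batchnorm <- function(name, ch, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", name = name, ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

layer_maxpool <- function(name, size = 2) {
  list(type = "maxpool", name = name, size = size, params = list())
}

layer_dropout <- function(name, rate) {
  list(type = "dropout", name = name, rate = rate, params = list())
}

layer_gap <- function(name) list(type = "gap", name = name, params = list())

layer_flatten <- function(name) list(type = "flatten", name = name, params = list())

layer_dense <- function(name, in_units, units,
                        activation = c("linear", "relu"), l2 = 0) {
  activation <- match.arg(activation)
  list(type = "dense", name = name, in_units = in_units, units = units,
       activation = activation, l2 = l2,
       params = list(W = .he_init(in_units, units, in_units),
                     b = numeric(units)))
}

layer_timedense <- function(name, in_units, units,
                            activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  list(type = "timedense", name = name, in_units = in_units, units = units,
       activation = activation,
       params = list(W = .he_init(in_units, units, in_units),
                     b = numeric(units)))
}

layer_layernorm <- function(name, ch, eps = 1e-5) {
  list(type = "layernorm", name = name, ch = ch, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)))
}

layer_encoder <- function(name, d, heads, ff = 2 * d, dropout = 0.1) {
  if (d %% heads != 0) stopf("projection dim %d not divisible by %d heads", d, heads)
  list(type = "encoder", name = name, d = d, heads = heads, ff = ff,
       dropout = dropout, eps = 1e-5,
       params = list(
         Wq = .he_init(d, d, d), bq = numeric(d),
         Wk = .he_init(d, d, d), bk = numeric(d),
         Wv = .he_init(d, d, d), bv = numeric(d),
         Wo = .he_init(d, d, d), bo = numeric(d),
         W1 = .he_init(d, ff, d), b1 = numeric(ff),
         W2 = .he_init(ff, d, ff), b2 = numeric(d),
         ln1_gamma = rep(1, d), ln1_beta = numeric(d),
         ln2_gamma = rep(1, d), ln2_beta = numeric(d)))
}

# ---- forward ----------------------------------------------------------------

.as_btc <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1)) else x
}

.im2col <- function(xp, T_, k, C) {
  B <- dim(xp)[1]
  cols <- matrix(0, B * T_, k * C)
  for (j in seq_len(k))
    cols[, (j - 1) * C + seq_len(C)] <- matrix(xp[, j:(j + T_ - 1), , drop = FALSE], B * T_, C)
  cols
}

.layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv1d = {
      d <- dim(x); B <- d[1]; T_ <- d[2]; C <- d[3]
      if (C != layer$in_ch)
        stopf("layer %s expects %d channels, got %d", layer$name, layer$in_ch, C)
      p <- (layer$kernel - 1) / 2
      xp <- array(0, c(B, T_ + 2 * p, C))
      xp[, p + seq_len(T_), ] <- x
      Xc <- .im2col(xp, T_, layer$kernel, C)
      z <- .addrow(Xc %*% layer$params$W, layer$params$b)
      mask <- NULL
      if (layer$activation == "relu") { mask <- z > 0; z <- z * mask }
      list(out = array(z, c(B, T_, layer$filters)), layer = layer,
           cache = list(Xc = Xc, mask = mask, B = B, T_ = T_, C = C))
    },
    batchnorm = {
      d <- dim(x); B <- d[1]; T_ <- d[2]; C <- d[3]
      xm <- matrix(x, B * T_, C)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
        layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
        layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$running_mean; v <- layer$running_var
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      N <- nrow(xm)
      xhat <- (xm - rep(mu, each = N)) * rep(inv_sd, each = N)
      y <- .addrow(xhat * rep(layer$params$gamma, each = N), layer$params$beta)
      list(out = array(y, d), layer = layer,
           cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, training = training))
    },
    maxpool = {
      d <- dim(x); B <- d[1]; T_ <- d[2]; C <- d[3]
      To <- T_ %/% layer$size
      if (To < 1) stopf("layer %s: input length %d too short to pool", layer$name, T_)
      x1 <- x[, seq(1, To * 2, 2), , drop = FALSE]
      x2 <- x[, seq(2, To * 2, 2), , drop = FALSE]
      first <- x1 >= x2
      out <- x1
      out[!first] <- x2[!first]
      list(out = array(out, c(B, To, C)), layer = layer,
           cache = list(first = first, dims = d, To = To))
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- array(stats::runif(length(x)) >= layer$rate, dim(x) %||% length(x))
        out <- x * keep / (1 - layer$rate)
        list(out = out, layer = layer, cache = list(keep = keep))
      } else list(out = x, layer = layer, cache = list(keep = NULL))
    },
    gap = {
      d <- dim(x)
      xm <- matrix(x, d[1], d[2] * d[3])
      out <- vapply(seq_len(d[3]), function(c)
        rowMeans(xm[, (c - 1) * d[2] + seq_len(d[2]), drop = FALSE]),
        numeric(d[1]))
      list(out = matrix(out, d[1], d[3]), layer = layer, cache = list(dims = d))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), layer = layer, cache = list(dims = d))
    },
    dense = {
      z <- .addrow(x %*% layer$params$W, layer$params$b)
      mask <- NULL
      if (layer$activation == "relu") { mask <- z > 0; z <- z * mask }
      list(out = z, layer = layer, cache = list(x = x, mask = mask))
    },
    timedense = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      z <- .addrow(xm %*% layer$params$W, layer$params$b)
      mask <- NULL
      if (layer$activation == "relu") { mask <- z > 0; z <- z * mask }
      list(out = array(z, c(d[1], d[2], layer$units)), layer = layer,
           cache = list(xm = xm, mask = mask, dims = d))
    },
    layernorm = {
      d <- dim(x)
      xm <- matrix(x, d[1] * d[2], d[3])
      mu <- rowMeans(xm)
      v <- rowMeans((xm - mu)^2)
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - mu) * inv_sd
      y <- .addrow(xhat * rep(layer$params$gamma, each = nrow(xm)), layer$params$beta)
      list(out = array(y, d), layer = layer,
           cache = list(xhat = xhat, inv_sd = inv_sd, dims = d))
    },
    encoder = .encoder_forward(layer, x, training),
    stopf("unknown layer type %s", layer$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.softmax_rows <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  e / rowSums(e)
}

.ln_forward <- function(xm, gamma, beta, eps) {
  mu <- rowMeans(xm)
  v <- rowMeans((xm - mu)^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv_sd
  list(y = .addrow(xhat * rep(gamma, each = nrow(xm)), beta),
       xhat = xhat, inv_sd = inv_sd)
}

.ln_backward <- function(dout, cache, gamma) {
  dxhat <- dout * rep(gamma, each = nrow(dout))
  dx <- cache$inv_sd * (dxhat - rowMeans(dxhat) -
                          cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dgamma = colSums(dout * cache$xhat), dbeta = colSums(dout))
}

.encoder_forward <- function(layer, x, training) {
  d <- dim(x); B <- d[1]; T_ <- d[2]; D <- d[3]
  h <- layer$heads; dk <- D / h
  p <- layer$params
  xm <- matrix(x, B * T_, D)
  Q <- .addrow(xm %*% p$Wq, p$bq)
  K <- .addrow(xm %*% p$Wk, p$bk)
  V <- .addrow(xm %*% p$Wv, p$bv)
  # sample-last (T, D, B) layout feeds the compiled batched-attention kernel
  Qt <- aperm(array(Q, c(B, T_, D)), c(2, 3, 1))
  Kt <- aperm(array(K, c(B, T_, D)), c(2, 3, 1))
  Vt <- aperm(array(V, c(B, T_, D)), c(2, 3, 1))
  att <- .cpp_att_forward(Qt, Kt, Vt, h)
  O <- aperm(att$O, c(3, 1, 2))
  Om <- matrix(O, B * T_, D)
  A <- .addrow(Om %*% p$Wo, p$bo)
  keep1 <- NULL
  Ad <- A
  if (training && layer$dropout > 0) {
    keep1 <- matrix(stats::runif(length(A)) >= layer$dropout, nrow(A), ncol(A))
    Ad <- A * keep1 / (1 - layer$dropout)
  }
  R1 <- xm + Ad
  ln1 <- .ln_forward(R1, p$ln1_gamma, p$ln1_beta, layer$eps)
  x1 <- ln1$y
  Z1 <- .addrow(x1 %*% p$W1, p$b1)
  Hmask <- Z1 > 0
  H <- Z1 * Hmask
  F_ <- .addrow(H %*% p$W2, p$b2)
  keep2 <- NULL
  Fd <- F_
  if (training && layer$dropout > 0) {
    keep2 <- matrix(stats::runif(length(F_)) >= layer$dropout, nrow(F_), ncol(F_))
    Fd <- F_ * keep2 / (1 - layer$dropout)
  }
  R2 <- x1 + Fd
  ln2 <- .ln_forward(R2, p$ln2_gamma, p$ln2_beta, layer$eps)
  list(out = array(ln2$y, d), layer = layer,
       cache = list(xm = xm, Qt = Qt, Kt = Kt, Vt = Vt, Pc = att$P,
                    Om = Om, keep1 = keep1, ln1 = ln1, x1 = x1,
                    Hmask = Hmask, H = H, keep2 = keep2, ln2 = ln2,
                    dims = d,
                    attention = aperm(array(att$P, c(T_, T_, h, B)),
                                      c(4, 3, 1, 2))))
}

# ---- backward ---------------------------------------------------------------

.layer_backward <- function(layer, cache, dout) {
  p <- layer$params
  switch(layer$type,
    conv1d = {
      B <- cache$B; T_ <- cache$T_; C <- cache$C
      k <- layer$kernel; pd <- (k - 1) / 2
      dz <- matrix(dout, B * T_, layer$filters)
      if (!is.null(cache$mask)) dz <- dz * cache$mask
      dW <- crossprod(cache$Xc, dz)
      if (layer$l2 > 0) dW <- dW + 2 * layer$l2 * p$W
      db <- colSums(dz)
      dXc <- dz %*% t(p$W)
      dxp <- array(0, c(B, T_ + 2 * pd, C))
      for (j in seq_len(k)) {
        blk <- array(dXc[, (j - 1) * C + seq_len(C)], c(B, T_, C))
        dxp[, j:(j + T_ - 1), ] <- dxp[, j:(j + T_ - 1), , drop = FALSE] + blk
      }
      list(dx = dxp[, pd + seq_len(T_), , drop = FALSE], grads = list(W = dW, b = db))
    },
    batchnorm = {
      d <- cache$dims
      dm <- matrix(dout, d[1] * d[2], d[3])
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      N <- nrow(dm)
      dxhat <- dm * rep(p$gamma, each = N)
      if (cache$training) {
        dx <- (dxhat - rep(colMeans(dxhat), each = N) -
                 cache$xhat * rep(colMeans(dxhat * cache$xhat), each = N)) *
          rep(cache$inv_sd, each = N)
      } else {
        dx <- dxhat * rep(cache$inv_sd, each = N)
      }
      list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    maxpool = {
      d <- cache$dims; To <- cache$To
      dx <- array(0, d)
      dx[, seq(1, To * 2, 2), ] <- dout * cache$first
      dx[, seq(2, To * 2, 2), ] <- dx[, seq(2, To * 2, 2), , drop = FALSE] + dout * !cache$first
      list(dx = dx, grads = list())
    },
    dropout = {
      if (!is.null(cache$keep))
        list(dx = dout * cache$keep / (1 - layer$rate), grads = list())
      else list(dx = dout, grads = list())
    },
    gap = {
      d <- cache$dims
      dxm <- dout[, rep(seq_len(d[3]), each = d[2]), drop = FALSE] / d[2]
      list(dx = array(dxm, d), grads = list())
    },
    flatten = list(dx = array(dout, cache$dims), grads = list()),
    dense = {
      dz <- dout
      if (!is.null(cache$mask)) dz <- dz * cache$mask
      dW <- crossprod(cache$x, dz)
      if (layer$l2 > 0) dW <- dW + 2 * layer$l2 * p$W
      list(dx = dz %*% t(p$W), grads = list(W = dW, b = colSums(dz)))
    },
    timedense = {
      d <- cache$dims
      dz <- matrix(dout, d[1] * d[2], layer$units)
      if (!is.null(cache$mask)) dz <- dz * cache$mask
      list(dx = array(dz %*% t(p$W), d),
           grads = list(W = crossprod(cache$xm, dz), b = colSums(dz)))
    },
    layernorm = {
      d <- cache$dims
      dm <- matrix(dout, d[1] * d[2], d[3])
      bk <- .ln_backward(dm, cache, p$gamma)
      list(dx = array(bk$dx, d), grads = list(gamma = bk$dgamma, beta = bk$dbeta))
    },
    encoder = .encoder_backward(layer, cache, dout),
    stopf("unknown layer type %s", layer$type))
}

.encoder_backward <- function(layer, cache, dout) {
  d <- cache$dims; B <- d[1]; T_ <- d[2]; D <- d[3]
  h <- layer$heads; dk <- D / h
  p <- layer$params
  dm <- matrix(dout, B * T_, D)
  bk2 <- .ln_backward(dm, cache$ln2, p$ln2_gamma)
  dR2 <- bk2$dx
  dFd <- dR2
  dF <- if (!is.null(cache$keep2)) dFd * cache$keep2 / (1 - layer$dropout) else dFd
  dH <- dF %*% t(p$W2)
  dW2 <- crossprod(cache$H, dF); db2 <- colSums(dF)
  dZ1 <- dH * cache$Hmask
  dW1 <- crossprod(cache$x1, dZ1); db1 <- colSums(dZ1)
  dx1 <- dR2 + dZ1 %*% t(p$W1)
  bk1 <- .ln_backward(dx1, cache$ln1, p$ln1_gamma)
  dR1 <- bk1$dx
  dAd <- dR1
  dA <- if (!is.null(cache$keep1)) dAd * cache$keep1 / (1 - layer$dropout) else dAd
  dOm <- dA %*% t(p$Wo)
  dWo <- crossprod(cache$Om, dA); dbo <- colSums(dA)
  dOt <- aperm(array(dOm, c(B, T_, D)), c(2, 3, 1))
  gb <- .cpp_att_backward(cache$Qt, cache$Kt, cache$Vt, cache$Pc, dOt, h)
  dQ <- aperm(gb$dQ, c(3, 1, 2))
  dK <- aperm(gb$dK, c(3, 1, 2))
  dV <- aperm(gb$dV, c(3, 1, 2))
  dQm <- matrix(dQ, B * T_, D); dKm <- matrix(dK, B * T_, D); dVm <- matrix(dV, B * T_, D)
  xm <- cache$xm
  dxm <- dR1 + dQm %*% t(p$Wq) + dKm %*% t(p$Wk) + dVm %*% t(p$Wv)
  list(dx = array(dxm, d),
       grads = list(
         Wq = crossprod(xm, dQm), bq = colSums(dQm),
         Wk = crossprod(xm, dKm), bk = colSums(dKm),
         Wv = crossprod(xm, dVm), bv = colSums(dVm),
         Wo = dWo, bo = dbo, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
         ln1_gamma = bk1$dgamma, ln1_beta = bk1$dbeta,
         ln2_gamma = bk2$dgamma, ln2_beta = bk2$dbeta))
}

# ---- model-level API --------------------------------------------------------

#' Run a model forward
#'
#' @param model an `affect_nn` model (see [build_cnn()], [build_conformer()]).
#' @param x input: matrix (batch x length) for single-channel models or array
#'   (batch x time x channels).
#' @param training use batch statistics and dropout (default FALSE).
#' @return list with `out`, per-layer `caches`, and the (possibly updated)
#'   `model`.
#' @export
nn_forward <- function(model, x, training = FALSE) {
  a <- .as_btc(x)
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    step <- .layer_forward(model$layers[[i]], a, training)
    model$layers[[i]] <- step$layer
    caches[[i]] <- step$cache
    a <- step$out
  }
  list(out = a, caches = caches, model = model)
}

#' Backpropagate a gradient through a model
#'
#' @param model an `affect_nn` model.
#' @param caches the caches from [nn_forward()].
#' @param dout gradient with respect to the model output.
#' @return list with `grads` (per layer), `dx` (gradient wrt the input) and
#'   `layer_dx` (gradient wrt each layer's input, for attribution methods).
#' @export
nn_backward <- function(model, caches, dout) {
  L <- length(model$layers)
  grads <- vector("list", L)
  layer_dx <- vector("list", L)
  d <- dout
  for (i in rev(seq_len(L))) {
    bk <- .layer_backward(model$layers[[i]], caches[[i]], d)
    grads[[i]] <- bk$grads
    layer_dx[[i]] <- bk$dx
    d <- bk$dx
  }
  list(grads = grads, dx = d, layer_dx = layer_dx)
}

#' Total trainable parameter count of a model
#' @param model an `affect_nn` model.
#' @return integer.
#' @export
nn_param_count <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$params, length, 0L)), 0))
}

# deep copy of all parameters (and batchnorm running stats)
.nn_snapshot <- function(model) {
  lapply(model$layers, function(l)
    list(params = l$params,
         running_mean = l$running_mean, running_var = l$running_var))
}

.nn_restore <- function(model, snap) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running_mean)) {
      model$layers[[i]]$running_mean <- snap[[i]]$running_mean
      model$layers[[i]]$running_var <- snap[[i]]$running_var
    }
  }
  model
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(model) {
  list(t = 0,
       m = lapply(model$layers, function(l) lapply(l$params, function(p) p * 0)),
       v = lapply(model$layers, function(l) lapply(l$params, function(p) p * 0)))
}

.adam_step <- function(model, opt, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      opt$m[[i]][[nm]] <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * g
      opt$v[[i]][[nm]] <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- opt$m[[i]][[nm]] / c1
      vhat <- opt$v[[i]][[nm]] / c2
      model$layers[[i]]$params[[nm]] <-
        model$layers[[i]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(model = model, opt = opt)
}

# ---- losses -----------------------------------------------------------------

#' Softmax over rows
#' @param z numeric matrix of logits.
#' @return matrix of row-stochastic probabilities.
#' @export
softmax <- function(z) .softmax_rows(as.matrix(z))

# classification loss + gradient wrt logits. labels are 0-based integers.
.clf_loss_grad <- function(logits, labels, class_weights = NULL,
                           loss = c("ce", "focal"), gamma = 2,
                           want_grad = TRUE) {
  loss <- match.arg(loss)
  B <- nrow(logits)
  probs <- .softmax_rows(logits)
  iy <- cbind(seq_len(B), labels + 1L)
  py <- pmax(probs[iy], 1e-12)
  w <- if (is.null(class_weights)) rep(1, B) else class_weights[labels + 1L]
  if (loss == "ce") {
    lval <- mean(w * -log(py))
    if (!want_grad) return(list(loss = lval, probs = probs))
    dlog <- probs
    dlog[iy] <- dlog[iy] - 1
    dlog <- dlog * (w / B)
    list(loss = lval, grad = dlog, probs = probs)
  } else {
    lval <- mean(w * -(1 - py)^gamma * log(py))
    if (!want_grad) return(list(loss = lval, probs = probs))
    g <- w * (gamma * (1 - py)^(gamma - 1) * log(py) - (1 - py)^gamma / py)
    dlog <- probs * (-py * g / B)
    dlog[iy] <- dlog[iy] + py * g / B
    list(loss = lval, grad = dlog, probs = probs)
  }
}

#' Focal loss of a batch of predicted probabilities
#'
#' Mean over the batch of `-alpha_y (1 - p_y)^gamma log(p_y)` (natural log).
#' With `gamma = 0` and unit `alpha` this reduces to cross-entropy. The true
#' class probability is clamped at 1e-12.
#'
#' @param probs row-stochastic matrix of predicted class probabilities.
#' @param labels 0-based integer class labels.
#' @param gamma focusing exponent (default 2).
#' @param alpha per-class weights (default all 1).
#' @return scalar loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2, alpha = NULL) {
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stopf("probs rows must sum to 1")
  B <- nrow(probs)
  py <- pmax(probs[cbind(seq_len(B), labels + 1L)], 1e-12)
  a <- if (is.null(alpha)) rep(1, B) else alpha[labels + 1L]
  mean(-a * (1 - py)^gamma * log(py))
}

#' Smooth-L1 (Huber) loss
#'
#' Elementwise `e^2 / 2` for `|e| < beta` and `beta * (|e| - beta / 2)`
#' otherwise (`beta = 1` by default), averaged over all elements.
#'
#' @param pred,target numeric arrays of equal shape.
#' @param beta quadratic-to-linear threshold (default 1).
#' @return scalar loss.
#' @export
smooth_l1 <- function(pred, target, beta = 1) {
  e <- abs(pred - target)
  mean(ifelse(e < beta, e^2 / (2 * beta), e - beta / 2))
}

.smooth_l1_grad <- function(pred, target, beta = 1) {
  e <- pred - target
  g <- ifelse(abs(e) < beta, e / beta, sign(e))
  g / length(e)
}

# L2 penalty contributed by the regularized layers
.l2_penalty <- function(model) {
  s <- 0
  for (l in model$layers)
    if (!is.null(l$l2) && l$l2 > 0) s <- s + l$l2 * sum(l$params$W^2)
  s
}
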
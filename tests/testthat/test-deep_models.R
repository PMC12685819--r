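test_that("the CNN has the specified layer order and output distribution", {
  m <- build_cnn(62, 3, seed = 1)
  expect_identical(vapply(m$layers, function(l) l$type, ""),
                   c("conv1d", "batchnorm", "maxpool", "dropout",
                     "conv1d", "batchnorm", "maxpool", "dropout",
                     "gap", "dense", "dropout", "dense"))
  probs <- predict_classes(m, matrix(rnorm(5 * 62), 5, 62))$probs
  expect_identical(dim(probs), c(5L, 3L))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
})

test_that("the parameter count equals the closed-form layer sum", {
  m <- build_cnn(62, 3, seed = 1)
  expected <- (3 * 1 * 64 + 64) + 2 * 64 +      # conv1 + bn1
    (3 * 64 * 128 + 128) + 2 * 128 +            # conv2 + bn2
    (128 * 64 + 64) + (64 * 3 + 3)              # dense + head
  expect_identical(nn_param_count(m), expected)
})

test_that("inputs too short for two pooling stages are rejected", {
  expect_error(build_cnn(3, 3), "too short")
})

test_that("balanced class weights follow n / (k * n_c)", {
  labels <- rep(0:2, c(10746, 3460, 6142))
  w <- compute_class_weights(labels)
  expect_equal(w, c(0.6312, 1.9603, 1.1043), tolerance = 1e-4)
  expect_equal(sum(table(labels) * w), length(labels), tolerance = 1e-9)
  expect_equal(compute_class_weights(rep(0:3, each = 5)), rep(1, 4))
  set.seed(50)
  lab <- sample(0:4, 300, replace = TRUE)
  expect_equal(sum(table(lab) * compute_class_weights(lab)), 300,
               tolerance = 1e-9)
  expect_error(compute_class_weights(c(0L, 0L, 2L)), "empty class")
})

test_that("focal loss reduces to cross-entropy and matches hand values", {
  probs <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2, byrow = TRUE)
  labels <- c(0L, 1L)
  expect_equal(focal_loss(probs, labels, gamma = 0),
               mean(-log(c(0.5, 0.8))), tolerance = 1e-12)
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 0L, gamma = 2),
               0.25 * log(2), tolerance = 1e-12)
  expect_equal(focal_loss(matrix(c(1, 0), 1), 0L, gamma = 2), 0)
})

test_that("smooth-L1 follows the quadratic and linear branches", {
  expect_equal(smooth_l1(0.5, 0), 0.125)
  expect_equal(smooth_l1(2, 0), 1.5)
  expect_equal(smooth_l1(c(0.5, 2), c(0, 0)), (0.125 + 1.5) / 2)
})

test_that("the plateau schedule halves on stagnation and floors at min_lr", {
  # an improving first epoch, then a flat stream
  lrs <- plateau_schedule(c(1, rep(1, 14)), lr0 = 1e-3, factor = 0.5,
                          patience = 1, min_lr = 1e-6)
  expect_equal(lrs[1:4], c(1e-3, 1e-3, 5e-4, 2.5e-4))
  expect_equal(min(lrs), 1e-6)
  expect_true(all(diff(lrs) <= 0))
  # improvements reset the wait counter
  lrs2 <- plateau_schedule(c(1, 0.9, 0.95, 0.8), patience = 2)
  expect_equal(lrs2, rep(1e-3, 4))
})

test_that("analytic gradients match finite differences on the CNN", {
  set.seed(3)
  m <- build_cnn(16, 3, dropout = 0, l2_coeff = 1e-3, seed = 5)
  x <- matrix(rnorm(6 * 16), 6, 16)
  y <- sample(0:2, 6, replace = TRUE)
  lossfun <- function(mm, xx, yy) {
    fw <- nn_forward(mm, xx, training = TRUE)
    affectkit:::.clf_loss_grad(fw$out, yy, c(0.5, 1, 2), "focal", 2,
                               want_grad = FALSE)$loss +
      affectkit:::.l2_penalty(mm)
  }
  fw <- nn_forward(m, x, training = TRUE)
  lg <- affectkit:::.clf_loss_grad(fw$out, y, c(0.5, 1, 2), "focal", 2)
  bk <- nn_backward(m, fw$caches, lg$grad)
  set.seed(99)
  for (r in 1:30) {
    li <- sample(seq_along(m$layers), 1)
    pns <- names(m$layers[[li]]$params)
    if (!length(pns)) next
    pn <- sample(pns, 1)
    idx <- sample(length(m$layers[[li]]$params[[pn]]), 1)
    ng <- numeric_param_grad(m, x, y, li, pn, idx, lossfun)
    ag <- bk$grads[[li]][[pn]][idx]
    expect_lt(abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)), 1e-4)
  }
})

test_that("analytic gradients match finite differences on the conformer", {
  m <- build_conformer(input_len = 10, projection_dim = 16, n_heads = 4,
                       ff_dim = 24, dropout = 0, seed = 7)
  x <- matrix(rnorm(4 * 10), 4, 10)
  y <- matrix(runif(12), 4, 3)
  lossfun <- function(mm, xx, yy)
    smooth_l1(nn_forward(mm, xx, training = TRUE)$out, yy)
  fw <- nn_forward(m, x, training = TRUE)
  bk <- nn_backward(m, fw$caches, affectkit:::.smooth_l1_grad(fw$out, y))
  set.seed(98)
  for (r in 1:40) {
    li <- sample(seq_along(m$layers), 1)
    pns <- names(m$layers[[li]]$params)
    if (!length(pns)) next
    pn <- sample(pns, 1)
    idx <- sample(length(m$layers[[li]]$params[[pn]]), 1)
    ng <- numeric_param_grad(m, x, y, li, pn, idx, lossfun)
    ag <- bk$grads[[li]][[pn]][idx]
    expect_lt(abs(ng - ag) / max(1e-6, abs(ng) + abs(ag)), 1e-4)
  }
})

test_that("training is deterministic and restores the best weights", {
  tab <- gen_stress_table(400, 10, effect_size = 2, seed = 23)
  xtr <- tab$values[1:300, ]; ytr <- tab$labels[1:300]
  xva <- tab$values[301:400, ]; yva <- tab$labels[301:400]
  cfg <- train_config(max_epochs = 6, batch_size = 64, seed = 23)
  run1 <- train_classifier(build_cnn(10, 3, seed = 23), xtr, ytr, xva, yva, cfg)
  run2 <- train_classifier(build_cnn(10, 3, seed = 23), xtr, ytr, xva, yva, cfg)
  expect_equal(run1$history$train_loss, run2$history$train_loss,
               tolerance = 1e-6)
  expect_equal(run1$history$val_loss, run2$history$val_loss, tolerance = 1e-6)
  # restored weights reproduce the best epoch's validation loss
  fw <- nn_forward(run1$model, xva, training = FALSE)
  best <- affectkit:::.clf_loss_grad(fw$out, yva, NULL, "ce",
                                     want_grad = FALSE)$loss
  expect_equal(best, min(run1$history$val_loss), tolerance = 1e-9)
  expect_true(all(diff(run1$history$lr) <= 0))
})

test_that("the conformer emits 3 outputs and row-stochastic attention", {
  m <- build_conformer(seed = 9)
  x <- matrix(rnorm(8 * 33), 8, 33)
  out <- predict_vad(m, x)
  expect_identical(dim(out), c(8L, 3L))
  att <- extract_attention(m, x[1, ])
  expect_identical(dim(att), c(2L, 4L, 33L, 33L))
  sums <- apply(att, c(1, 2, 3), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-6)
})

test_that("fine-tuning loads the backbone bitwise and rebuilds the head", {
  pre <- build_cnn(62, 3, seed = 31)
  bundle <- model_to_checkpoint(pre)
  aw <- gen_activity_windows(60, proportions = rep(0.25, 4),
                             window_samples = 16, n_channels = 2,
                             effect_size = 2, seed = 31)
  x <- flatten_windows(aw$windows)
  zero_cfg <- train_config(lr = 1e-4, max_epochs = 0, seed = 31)
  ft <- fine_tune(bundle, x, aw$labels, x, aw$labels, n_classes = 4,
                  config = zero_cfg)
  for (nm in c("conv1", "bn1", "conv2", "bn2", "dense")) {
    i_pre <- which(vapply(pre$layers, function(l) l$name, "") == nm)
    i_ft <- which(vapply(ft$model$layers, function(l) l$name, "") == nm)
    expect_identical(ft$model$layers[[i_ft]]$params,
                     pre$layers[[i_pre]]$params)
  }
  head <- ft$model$layers[[length(ft$model$layers)]]
  expect_identical(dim(head$params$W), c(64L, 4L))
  expect_identical(dim(predict_classes(ft$model, x)$probs), c(60L, 4L))
})

test_that("incompatible backbone shapes are rejected at load time", {
  pre <- build_cnn(62, 3, filters1 = 32, seed = 1)   # 32-filter conv1
  bundle <- model_to_checkpoint(pre)
  target <- build_cnn(62, 4, seed = 2)               # expects 64 filters
  expect_error(load_weights_into(target, bundle, skip = "head"),
               "incompatible backbone shape")
})
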
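# toy single-conv model: one filter with identity center tap, then GAP and
# a linear head, so the heatmap is hand-traceable.
toy_conv_model <- function(channels = 1, head_w = 1) {
  set.seed(1)
  conv <- affectkit:::layer_conv1d("conv2", channels, 1, 3, "relu")
  conv$params$W[] <- 0
  conv$params$W[2 * channels - (channels - 1), 1] <- head_w  # center tap, ch 1
  if (channels == 2) conv$params$W[4, 1] <- 0                # ignore channel 2
  head <- affectkit:::layer_dense("head", 1, 2, "linear")
  head$params$W[] <- c(1, -1)
  head$params$b[] <- 0
  structure(list(layers = list(conv, affectkit:::layer_gap("gap"), head),
                 kind = "cnn1d", input_len = 16, input_channels = channels,
                 n_classes = 2), class = "affect_nn")
}

test_that("Grad-CAM peaks at an impulse for a hand-traceable conv net", {
  m <- toy_conv_model()
  x <- numeric(16); x[9] <- 1
  cam <- grad_cam_1d(m, x, target_class = 0, conv_layer = "conv2")
  expect_length(cam$values, 16)
  expect_identical(which.max(cam$values), 9L)
  expect_equal(max(cam$values), 1)
  expect_true(all(cam$values >= 0 & cam$values <= 1))
})

test_that("Grad-CAM heatmaps align with inputs of length 62 and 640", {
  for (len in c(62, 640)) {
    m <- build_cnn(len, 3, seed = 4)
    set.seed(4)
    cam <- grad_cam_1d(m, rnorm(len), target_class = 1)
    expect_length(cam$values, len)
    expect_true(all(cam$values >= 0 & cam$values <= 1))
  }
})

test_that("a flat (all-negative) map degenerates to zeros, not NaN", {
  m <- toy_conv_model()
  x <- numeric(16); x[9] <- 1
  # class 1 has head weight -1: the CAM is all negative before the ReLU
  cam <- grad_cam_1d(m, x, target_class = 1, conv_layer = "conv2")
  expect_equal(cam$values, rep(0, 16))
})

test_that("invalid layers and classes are rejected", {
  m <- build_cnn(32, 3, seed = 2)
  expect_error(grad_cam_1d(m, rnorm(32), 0, conv_layer = "gap"),
               "not convolutional")
  expect_error(grad_cam_1d(m, rnorm(32), 7), "out of range")
})

test_that("multichannel Grad-CAM reduces to the 1D map for one channel", {
  m <- build_cnn(48, 2, seed = 6)
  set.seed(6)
  x <- rnorm(48)
  mc <- grad_cam_multichannel(m, matrix(x, ncol = 1), target_class = 0)
  one <- grad_cam_1d(m, x, target_class = 0)
  expect_equal(as.numeric(mc$values[1, ]), one$values, tolerance = 1e-12)
  expect_equal(max(mc$values), 1)
})

test_that("channel relevance concentrates on the sensitive channel", {
  m <- toy_conv_model(channels = 2)
  set.seed(7)
  x <- matrix(rnorm(32, sd = 0.2), 16, 2)
  x[9, 1] <- 2
  mc <- grad_cam_multichannel(m, x, target_class = 0, conv_layer = "conv2")
  expect_gt(sum(mc$values[1, ]), sum(mc$values[2, ]))
  expect_identical(dim(mc$values), c(2L, 16L))
  expect_equal(max(mc$values), 1)
})

test_that("integrated gradients are exact for a linear model", {
  set.seed(8)
  w <- rnorm(10)
  dense <- affectkit:::layer_dense("head", 10, 1, "linear")
  dense$params$W[] <- w; dense$params$b[] <- 0.3
  m <- structure(list(layers = list(affectkit:::layer_flatten("flat"), dense),
                      kind = "linear", input_len = 10, input_channels = 1,
                      n_classes = 1), class = "affect_nn")
  x <- rnorm(10)
  ig <- integrated_gradients(m, x, target = 0, steps = 7)
  expect_equal(ig$attributions, w * x, tolerance = 1e-10)
  expect_lt(abs(ig$completeness_gap), 1e-10)
  ig0 <- integrated_gradients(m, numeric(10), target = 0)
  expect_equal(ig0$attributions, rep(0, 10))
})

test_that("the completeness gap shrinks as the Riemann grid refines", {
  m <- build_cnn(24, 2, dropout = 0, seed = 9)
  set.seed(9)
  x <- rnorm(24)
  gaps <- vapply(c(10, 50, 200), function(s)
    abs(integrated_gradients(m, x, target = 0, steps = s)$completeness_gap), 0)
  expect_lte(gaps[3], gaps[1] + 1e-8)
  fx <- nn_forward(m, matrix(x, 1))$out[1, 1]
  f0 <- nn_forward(m, matrix(numeric(24), 1))$out[1, 1]
  expect_lt(gaps[3], 0.05 * max(abs(fx - f0), 0.1))
})

test_that("attention extraction yields stochastic rows of the right shape", {
  m <- build_conformer(seed = 10)
  set.seed(10)
  att <- extract_attention(m, rnorm(33))
  expect_identical(dim(att), c(2L, 4L, 33L, 33L))
  expect_true(all(abs(apply(att, c(1, 2, 3), sum) - 1) < 1e-6))
  expect_true(all(att >= 0))
})

test_that("zeroed query projections give uniform attention rows", {
  m <- build_conformer(seed = 11)
  for (i in seq_along(m$layers)) {
    if (m$layers[[i]]$type == "encoder") {
      m$layers[[i]]$params$Wq[] <- 0
      m$layers[[i]]$params$bq[] <- 0
    }
  }
  att <- extract_attention(m, rnorm(33))
  expect_equal(as.numeric(att), rep(1 / 33, length(att)), tolerance = 1e-9)
})

test_that("t-SNE is deterministic and separates well-separated clusters", {
  set.seed(12)
  feats <- rbind(matrix(rnorm(50 * 8, mean = 0), 50, 8),
                 matrix(rnorm(50 * 8, mean = 6), 50, 8))
  labels <- rep(0:1, each = 50)
  y1 <- tsne_embed(feats, perplexity = 30, seed = 3)
  y2 <- tsne_embed(feats, perplexity = 30, seed = 3)
  expect_identical(dim(y1), c(100L, 2L))
  expect_identical(y1, y2)
  expect_gt(silhouette_mean(y1, labels), 0.5)
  expect_error(tsne_embed(feats[1:20, ], perplexity = 30), "perplexity")
})
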
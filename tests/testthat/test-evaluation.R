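# the published confusion counts of the three-class stress classifier,
# used as a fixed worked example throughout
published_confusion <- matrix(c(10401, 247, 98,
                                21, 3438, 1,
                                18, 8, 6116), 3, 3, byrow = TRUE)

test_that("confusion matrices count true/predicted pairs with exact supports", {
  y_true <- c(0, 0, 1, 1, 2, 2, 2)
  y_pred <- c(0, 1, 1, 1, 2, 2, 0)
  m <- confusion_matrix(y_true, y_pred, 3)
  expect_identical(as.integer(rowSums(m)), c(2L, 2L, 3L))
  expect_identical(sum(m), length(y_true))
  expect_identical(m[3, 1], 1L)
  perfect <- confusion_matrix(0:2, 0:2, 3)
  expect_identical(unname(diag(perfect)), rep(1L, 3))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "out of range")
  expect_identical(as.integer(rowSums(published_confusion)),
                   c(10746L, 3460L, 6142L))
})

test_that("the report reproduces every printed cell of the worked example", {
  rep <- classification_report(published_confusion)
  r2 <- function(x) round_half_away(x, 2)
  expect_equal(r2(rep$per_class$precision), c(1.00, 0.93, 0.98))
  expect_equal(r2(rep$per_class$recall), c(0.97, 0.99, 1.00))
  expect_equal(r2(rep$per_class$f1), c(0.98, 0.96, 0.99))
  expect_equal(rep$accuracy, 19955 / 20348, tolerance = 1e-12)
  expect_equal(r2(rep$accuracy), 0.98)
  expect_equal(r2(rep$macro["precision"]), 0.97, ignore_attr = TRUE)
  expect_equal(r2(rep$macro["recall"]), 0.99, ignore_attr = TRUE)
  expect_equal(r2(rep$macro["f1"]), 0.98, ignore_attr = TRUE)
  expect_equal(unname(r2(rep$weighted)), c(0.98, 0.98, 0.98))
  expect_identical(sum(rep$per_class$support), 20348)
})

test_that("weighted recall equals accuracy for any confusion matrix", {
  set.seed(71)
  for (r in 1:20) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 20), k, k)
    diag(m) <- diag(m) + rpois(k, 50)
    rep <- classification_report(m)
    expect_equal(unname(rep$weighted["recall"]), rep$accuracy,
                 tolerance = 1e-12)
  }
})

test_that("degenerate matrices are handled", {
  rep <- suppressWarnings(classification_report(matrix(c(5, 0, 0, 0), 2, 2)))
  expect_equal(rep$per_class$precision[1], 1)
  expect_equal(rep$accuracy, 1)
  expect_warning(classification_report(matrix(c(5, 0, 1, 0), 2, 2,
                                              byrow = TRUE)),
                 "never predicted")
  expect_error(classification_report(matrix(0, 2, 2)), "empty")
})

test_that("regression metrics match the hand-computed two-point example", {
  met <- regression_metrics(matrix(c(0.3, 0.8)), matrix(c(0, 1)))
  expect_equal(met$mae, 0.25)
  expect_equal(met$rmse, sqrt(0.065), tolerance = 1e-12)
  expect_equal(met$r2, 1 - 0.13 / 0.5, tolerance = 1e-12)
})

test_that("perfect and constant-offset predictions give the obvious metrics", {
  set.seed(72)
  y <- matrix(runif(60), 20, 3)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rounded_accuracy_all, 100)
  expect_equal(unname(perfect$rounded_accuracy_per_dim), rep(100, 3))
  off <- regression_metrics(y + 0.1, y)
  expect_equal(off$mae, 0.1, tolerance = 1e-12)
  expect_equal(off$rmse, 0.1, tolerance = 1e-12)
})

test_that("rmse dominates mae and joint rounded accuracy is the floor", {
  set.seed(73)
  for (r in 1:20) {
    y <- matrix(runif(90), 30, 3)
    p <- y + matrix(rnorm(90, 0, 0.2), 30, 3)
    met <- regression_metrics(p, y)
    expect_gte(met$rmse, met$mae)
    expect_lte(met$rounded_accuracy_all, min(met$rounded_accuracy_per_dim))
  }
})

test_that("a constant target dimension makes R-squared an error", {
  y <- cbind(runif(10), rep(0.5, 10))
  expect_error(regression_metrics(y, y), "constant target dimension")
  expect_error(regression_metrics(matrix(1, 3, 2), matrix(1, 2, 2)),
               "shapes differ")
})

test_that("smooth-L1 in the report equals the standalone loss", {
  set.seed(74)
  y <- matrix(runif(30), 10, 3)
  p <- y + 0.3
  expect_equal(regression_metrics(p, y)$smooth_l1, smooth_l1(p, y))
})
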
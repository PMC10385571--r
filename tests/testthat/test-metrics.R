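test_that("rmse matches hand arithmetic and the brute-force oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1.0)
  expect_equal(rmse(c(0, 0, 0, 0), c(1, 2, 3, 4)), sqrt(30 / 4))
  set.seed(42)
  for (k in 1:25) {
    y <- rnorm(17)
    yh <- rnorm(17)
    expect_equal(rmse(y, yh), oracle_rmse(y, yh), tolerance = 1e-12)
  }
})

test_that("rmse on matrices reports per-channel values and their mean", {
  y <- cbind(a = c(0, 0), b = c(0, 0))
  yh <- cbind(a = c(1, 1), b = c(3, 3))
  r <- rmse(y, yh)
  expect_equal(unname(r$per_channel), c(1, 3))
  expect_equal(r$mean, 2)
  expect_error(rmse(1:3, 1:4), "identical shape")
})

test_that("pearson_corr matches the closed form and the oracle", {
  y <- 1:10
  expect_equal(pearson_corr(y, 2 * y + 3), 1.0)
  y0 <- y - mean(y)
  expect_equal(pearson_corr(y0, -y0), -1.0)
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  set.seed(7)
  for (k in 1:25) {
    a <- rnorm(23)
    b <- rnorm(23)
    expect_equal(pearson_corr(a, b), oracle_corr(a, b), tolerance = 1e-12)
  }
})

test_that("pearson_corr is invariant under positive affine transforms", {
  set.seed(11)
  a <- rnorm(50)
  b <- rnorm(50)
  r0 <- pearson_corr(a, b)
  expect_equal(pearson_corr(3 * a + 2, b), r0, tolerance = 1e-12)
  expect_equal(pearson_corr(a, 0.5 * b - 7), r0, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("classification_report reproduces one-vs-rest counting", {
  # perfect predictions
  r <- classification_report(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(r$accuracy_overall, 1)
  expect_true(all(r$per_class$precision == 1))
  expect_true(all(r$per_class$f1 == 1))
  expect_equal(unname(diag(r$confusion)), c(1L, 1L, 1L))

  # binary toy with Tp=3, Tn=5, Fp=1, Fn=1 for the positive class
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  r <- classification_report(truth, pred)
  pos <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pos$tp, 3L)
  expect_equal(pos$tn, 5L)
  expect_equal(pos$fp, 1L)
  expect_equal(pos$fn, 1L)
  expect_equal(pos$accuracy, 0.8)
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$f1, 0.75)

  # collapsing to one predicted class in a balanced 5-class set of 100
  labs <- paste0("c", 1:5)
  truth <- rep(labs, each = 20)
  pred <- rep("c1", 100)
  r <- classification_report(truth, pred, labels = labs)
  expect_equal(r$accuracy_overall, 0.2)
  c1 <- r$per_class[r$per_class$class == "c1", ]
  expect_equal(c1$accuracy, 0.2)
  expect_equal(sum(r$confusion), 100L)
})

test_that("classification_report agrees with the counting oracle on random labelings", {
  set.seed(3)
  labs <- c("w", "x", "y", "z")
  for (k in 1:10) {
    truth <- sample(labs, 60, replace = TRUE)
    pred <- sample(labs, 60, replace = TRUE)
    r <- classification_report(truth, pred, labels = labs)
    o <- oracle_class_metrics(truth, pred, labs)
    for (cl in labs) {
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(row$accuracy, unname(o[[cl]]["accuracy"]))
      expect_equal(row$f1, unname(o[[cl]]["f1"]))
    }
    # confusion row sums are per-class true counts
    expect_equal(unname(rowSums(r$confusion)),
                 unname(vapply(labs, function(l) sum(truth == l), 1)))
  }
  expect_error(classification_report(c("a", "b"), "a"), "same length")
})

test_that("forecast_metrics averages per epoch within activity, then adds a grand mean", {
  set.seed(5)
  truths <- replicate(4, matrix(rnorm(20), 10, 2), simplify = FALSE)
  fcs <- lapply(truths, function(m) m + rnorm(20, sd = 0.1))
  fm <- forecast_metrics(truths, fcs, c("walk", "walk", "run", "run"))
  expect_equal(fm$activity, c("run", "walk", "mean"))
  expect_equal(fm$rmse[3], mean(fm$rmse[1:2]))
  expect_equal(fm$n_epochs[3], 4L)
  expect_true(all(fm$corr <= 1 & fm$corr >= -1))
})
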
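# two synthetic classes in disjoint frequency bands (trivially separable)
separable_windows <- function(n_per_class = 20, len = 64, ch = 3, seed = 1,
                              f = c(lowband = 3, highband = 12)) {
  set.seed(seed)
  X <- array(0, c(2 * n_per_class, len, ch))
  lab <- rep(names(f), each = n_per_class)
  t <- (0:(len - 1)) / 100
  for (i in seq_len(2 * n_per_class)) {
    ph <- runif(1, 0, 2 * pi)
    for (c in seq_len(ch)) {
      X[i, , c] <- sin(2 * pi * f[[lab[i]]] * t + ph + c) +
        rnorm(len, sd = 0.05)
    }
  }
  list(x = X, label = lab)
}

test_that("classifier outputs a normalized probability vector over classes", {
  spec <- classifier_spec(input_len = 256L, bilstm_units = c(8L, 4L),
                          hidden_neurons = 16L, seed = 1L)
  cl <- build_classifier(spec)
  set.seed(2)
  out <- classify_signal(cl, matrix(rnorm(256 * 6), 256, 6))
  probs <- as.numeric(out[1, hap_activities()])
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  expect_true(all(probs >= 0))
  expect_equal(out$label, hap_activities()[which.max(probs)])
  expect_error(classify_signal(cl, matrix(0, 10, 6)), "input must be")
  # seeded build determinism
  expect_identical(build_classifier(spec)$params, cl$params)
})

test_that("the first bidirectional layer concatenates forward and backward widths", {
  spec <- classifier_spec(input_len = 12L, n_channels = 2L,
                          bilstm_units = c(5L, 3L), hidden_neurons = 8L,
                          classes = c("a", "b"), seed = 3L)
  cl <- build_classifier(spec)
  X <- array(rnorm(2 * 2 * 12), c(2, 2, 12))
  fw <- hapr:::cl_fwd(cl$params, X, spec)
  expect_equal(dim(fw$cache$f1$H)[2] + dim(fw$cache$b1$H)[2], 2L * 5L)
  expect_equal(ncol(fw$logits), 2L)
})

test_that("reversing input and swapping direction blocks mirrors hidden states", {
  spec <- classifier_spec(input_len = 10L, n_channels = 2L,
                          bilstm_units = c(4L, 3L), hidden_neurons = 8L,
                          classes = c("a", "b"), seed = 4L)
  cl <- build_classifier(spec)
  set.seed(5)
  X <- array(rnorm(1 * 2 * 10), c(1, 2, 10))
  fw1 <- hapr:::cl_fwd(cl$params, X, spec)
  swapped <- cl$params
  swapped[c("f1", "b1", "f2", "b2")] <- cl$params[c("b1", "f1", "b2", "f2")]
  fw2 <- hapr:::cl_fwd(swapped, hapr:::rev_time(X), spec)
  # the backward pass of the swapped model runs the original forward
  # parameters over the double-reversed (i.e. original) sequence, so its
  # states match the original forward states exactly
  expect_equal(fw2$cache$b1$H, fw1$cache$f1$H, tolerance = 1e-12)
  expect_equal(fw2$cache$f1$H, fw1$cache$b1$H, tolerance = 1e-12)
})

test_that("classification is invariant to batch composition", {
  spec <- classifier_spec(input_len = 32L, n_channels = 3L,
                          bilstm_units = c(6L, 4L), hidden_neurons = 12L,
                          classes = c("a", "b"), seed = 6L)
  cl <- build_classifier(spec)
  set.seed(7)
  X <- array(rnorm(5 * 32 * 3), c(5, 32, 3))
  full <- classify_signal(cl, X)
  one <- classify_signal(cl, X[3, , ])
  expect_equal(as.numeric(one[1, c("a", "b")]),
               as.numeric(full[3, c("a", "b")]), tolerance = 1e-12)
})

test_that("two separable frequency classes are learned almost perfectly", {
  tr <- separable_windows(n_per_class = 25, seed = 1)
  te <- separable_windows(n_per_class = 10, seed = 2)
  spec <- classifier_spec(input_len = 64L, n_channels = 3L,
                          bilstm_units = c(8L, 4L), hidden_neurons = 16L,
                          classes = c("lowband", "highband"), seed = 1L)
  cl <- build_classifier(spec)
  cl <- fit_classifier(cl, tr$x, tr$label,
                       train_config(passes = 40, batch_size = 10,
                                    learning_rate = 3e-3, seed = 1))
  expect_lt(cl$history$loss[nrow(cl$history)], cl$history$loss[1])
  pred <- classify_signal(cl, te$x)
  expect_gte(mean(pred$label == te$label), 0.95)
})

test_that("training rejects degenerate label sets and is seed-reproducible", {
  tr <- separable_windows(n_per_class = 4)
  spec <- classifier_spec(input_len = 64L, n_channels = 3L,
                          bilstm_units = c(4L, 3L), hidden_neurons = 8L,
                          classes = c("lowband", "highband"), seed = 1L)
  expect_error(fit_classifier(build_classifier(spec), tr$x,
                              rep("lowband", 8)), "single class")
  expect_error(fit_classifier(build_classifier(spec), tr$x,
                              rep(c("lowband", "zzz"), 4)), "outside")
  cfg <- train_config(passes = 4, batch_size = 4, learning_rate = 1e-3,
                      seed = 3)
  c1 <- fit_classifier(build_classifier(spec), tr$x, tr$label, cfg)
  c2 <- fit_classifier(build_classifier(spec), tr$x, tr$label, cfg)
  expect_identical(c1$params, c2$params)
  expect_identical(tidy(c1), tidy(c2))
  expect_equal(glance(c1)$n_classes, 2L)
})
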
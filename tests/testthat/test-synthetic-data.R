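test_that("a noiseless single-harmonic model reproduces the closed-form sine", {
  m <- activity_model(2.0, harmonics = 1, channel_gains = rep(1, 6),
                      channel_phases = rep(0, 6), noise_sd = 0)
  rec <- generate_recording(list(walk = m),
                            tibble::tibble(activity = "walk",
                                           duration_s = 2),
                            fs = 100, seed = 5)
  # the only stochastic term is the per-block phase offset
  set.seed(5)
  ph <- runif(1, 0, 2 * pi)
  t <- (0:199) / 100
  expect_equal(unname(rec$channels[, 1]), sin(2 * pi * 2 * t + ph),
               tolerance = 1e-12)
  expect_equal(unique(rec$activity_id), pamap2_activity_codes()[["walk"]])
})

test_that("recordings are reproducible from the seed", {
  models <- activity_models(noise_sd = 0.1, nan_rate = 0.01,
                            outlier_rate = 0.01)
  sched <- tibble::tibble(activity = c("walk", "run"), duration_s = c(3, 3))
  r1 <- generate_recording(models, sched, seed = 42)
  r2 <- generate_recording(models, sched, seed = 42)
  expect_identical(r1$channels, r2$channels)
  r3 <- generate_recording(models, sched, seed = 43)
  expect_false(identical(r1$channels, r3$channels))
  expect_error(generate_recording(models,
                                  tibble::tibble(activity = character(0),
                                                 duration_s = numeric(0))),
               "empty schedule")
})

test_that("artifact injection matches the binomial count oracle", {
  m <- activity_model(2.0, noise_sd = 0, nan_rate = 0.01, outlier_rate = 0)
  rec <- generate_recording(list(walk = m),
                            tibble::tibble(activity = "walk",
                                           duration_s = 1000),
                            fs = 100, seed = 7)
  n <- nrow(rec$channels) # 1e5 samples
  hits <- sum(rowSums(is.na(rec$channels)) > 0)
  expect_equal(n, 100000L)
  band <- 3 * sqrt(n * 0.01 * 0.99)
  expect_gt(hits, 1000 - band)
  expect_lt(hits, 1000 + band)
})

test_that("generated datasets are balanced and satisfy the epoch invariants", {
  ds <- generate_hap_dataset(epochs_per_class = 50, seed = 3)
  counts <- table(ds$train_epochs$label)
  expect_equal(length(counts), 5L)
  # balanced within one block of epochs
  expect_true(all(counts >= 50 & counts < 50 + 3))
  expect_true(all(is.finite(ds$train_epochs$data)))
  expect_true(all(abs(ds$train_epochs$data) <= 1))
  expect_equal(dim(ds$train_epochs$data)[2:3], c(512L, 6L))
  # pairs reconstruct the epochs
  expect_equal(dim(ds$train$observed)[2], 256L)
  i <- 7L
  expect_equal(rbind(ds$train$observed[i, , ], ds$train$future[i, , ]),
               epoch_matrix(ds$train_epochs, i))
})

test_that("epoch spectra recover each activity's fundamental within one FFT bin", {
  models <- activity_models(noise_sd = 0.01, nan_rate = 0, outlier_rate = 0)
  ds <- generate_hap_dataset(models, epochs_per_class = 6, seed = 11)
  fs <- 100
  len <- 512
  bin <- fs / len
  f0s <- vapply(models, `[[`, numeric(1), "fundamental_hz")
  for (i in seq_len(length(ds$test_epochs))) {
    x <- ds$test_epochs$data[i, , 1]
    sp <- Mod(stats::fft(x))[2:(len / 2 + 1)]
    fpeak <- which.max(sp) * bin
    expect_lt(abs(fpeak - f0s[[ds$test_epochs$label[i]]]), bin + 1e-9)
  }
})

test_that("a spectral-peak classifier certifies class separability", {
  models <- activity_models(noise_sd = 0.05)
  ds <- generate_hap_dataset(models, epochs_per_class = 20, seed = 2)
  pred <- spectral_peak_classify(ds$train_epochs, models)
  acc <- mean(pred == ds$train_epochs$label)
  expect_gte(acc, 0.99)
})

test_that("the future half is statistically continuous with the observed half", {
  # the jump across the epoch midpoint should look like an ordinary
  # one-sample increment, not a seam
  models <- activity_models(noise_sd = 0.02, nan_rate = 0, outlier_rate = 0)
  ds <- generate_hap_dataset(models, epochs_per_class = 10, seed = 6)
  n <- length(ds$train)
  seam <- abs(ds$train$future[, 1, ] - ds$train$observed[, 256, ])
  steps <- abs(ds$train$observed[, 2, ] - ds$train$observed[, 1, ])
  expect_lt(mean(seam), 3 * mean(steps) + 0.05)
})
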
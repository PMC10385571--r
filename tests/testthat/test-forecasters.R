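test_that("builds are seeded and deterministic; unknown architecture errors", {
  spec <- forecaster_spec("conv2lstm", input_len = 32L, output_len = 32L,
                          units = 8L, filters = 4L, seed = 7L)
  m1 <- build_forecaster(spec)
  m2 <- build_forecaster(spec)
  expect_identical(m1$params, m2$params)
  spec2 <- spec
  spec2$seed <- 8L
  expect_false(identical(build_forecaster(spec2)$params, m1$params))
  expect_error(forecaster_spec("transformer"), "arg")
  expect_error(forecaster_spec("seq2seq_lstm_pe_ma", d_model = 30,
                               n_heads = 4), "divisible")
  expect_error(forecaster_spec("conv2lstm", input_len = 128,
                               output_len = 256), "must equal")
})

test_that("forecasts have the contracted shape and are finite and repeatable", {
  for (arch in c("conv2lstm", "seq2seq_lstm", "seq2seq_lstm_pe_ma")) {
    spec <- forecaster_spec(arch, units = if (arch == "seq2seq_lstm_pe_ma")
      8L else 8L, d_model = 8L, n_heads = 2L, filters = 4L, seed = 1L)
    m <- build_forecaster(spec)
    obs <- matrix(0, 256, 6)
    y1 <- forecast_signal(m, obs)
    expect_equal(dim(y1), c(256L, 6L))
    expect_true(all(is.finite(y1)))
    # deterministic inference (dropout disabled)
    expect_identical(forecast_signal(m, obs), y1)
    # inference does not mutate parameters
    p0 <- m$params
    set.seed(99)
    invisible(forecast_signal(m, matrix(rnorm(256 * 6), 256, 6)))
    expect_identical(m$params, p0)
    expect_error(forecast_signal(m, matrix(0, 100, 6)), "must be")
  }
})

test_that("batched and single-epoch inference agree", {
  spec <- forecaster_spec("seq2seq_lstm", input_len = 64L, output_len = 64L,
                          n_channels = 2L, units = 8L, seed = 2L)
  m <- build_forecaster(spec)
  set.seed(3)
  X <- array(rnorm(3 * 64 * 2), c(3, 64, 2))
  batch <- forecast_signal(m, X)
  for (i in 1:3) {
    expect_equal(matrix(batch[i, , ], 64, 2), forecast_signal(m, X[i, , ]),
                 tolerance = 1e-12)
  }
})

test_that("training drives predictions to a constant-zero target", {
  spec <- forecaster_spec("conv2lstm", input_len = 32L, output_len = 32L,
                          n_channels = 3L, units = 8L, filters = 4L,
                          dropout = 0, seed = 1L)
  m <- build_forecaster(spec)
  set.seed(5)
  pairs <- list(observed = array(rnorm(10 * 32 * 3), c(10, 32, 3)),
                future = array(0, c(10, 32, 3)))
  m <- fit_forecaster(m, pairs, train_config(passes = 80, batch_size = 5,
                                             learning_rate = 3e-3, seed = 1))
  pred <- forecast_signal(m, pairs$observed)
  expect_lt(sqrt(mean(pred^2)), 0.05)
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
})

test_that("a small model can overfit a single repeated sinusoid pair", {
  pr <- tiny_pairs(n = 1, len = 32, ch = 3, seed = 2)
  spec <- forecaster_spec("seq2seq_lstm_pe_ma", input_len = 32L,
                          output_len = 32L, n_channels = 3L, units = 8L,
                          d_model = 8L, n_heads = 2L, seed = 1L)
  m <- build_forecaster(spec)
  m <- fit_forecaster(m, pr, train_config(passes = 240, batch_size = 1,
                                          learning_rate = 3e-3, seed = 1))
  pred <- forecast_signal(m, pr$observed[1, , ])
  expect_gte(pearson_corr(pr$future[1, , ], pred)$mean, 0.99)
})

test_that("training histories are reproducible under a fixed seed", {
  pr <- tiny_pairs(n = 6, len = 32, ch = 3, seed = 4)
  spec <- forecaster_spec("seq2seq_lstm", input_len = 32L, output_len = 32L,
                          n_channels = 3L, units = 6L, seed = 2L)
  cfg <- train_config(passes = 10, batch_size = 3, learning_rate = 1e-3,
                      teacher_forcing = FALSE, seed = 9)
  h1 <- fit_forecaster(build_forecaster(spec), pr, cfg)$history
  h2 <- fit_forecaster(build_forecaster(spec), pr, cfg)$history
  expect_identical(h1, h2)
  expect_error(fit_forecaster(build_forecaster(spec),
                              list(observed = array(0, c(0, 32, 3)),
                                   future = array(0, c(0, 32, 3))),
                              cfg),
               "empty")
})

test_that("tidiers expose history and model summary", {
  pr <- tiny_pairs(n = 2, len = 32, ch = 3)
  spec <- forecaster_spec("conv2lstm", input_len = 32L, output_len = 32L,
                          n_channels = 3L, units = 4L, filters = 4L,
                          seed = 1L)
  m <- fit_forecaster(build_forecaster(spec), pr,
                      train_config(passes = 3, batch_size = 2))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  gl <- glance(m)
  expect_equal(gl$architecture, "conv2lstm")
  expect_true(gl$trained)
  expect_equal(gl$final_loss, td$loss[3])
})
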
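test_that("clean_record trims edges and repairs artifacts with segment means", {
  fs <- 100
  n <- 80 * fs
  set.seed(1)
  ch <- cbind(rnorm(n), rnorm(n))
  rec <- hap_recording((seq_len(n) - 1) / fs, rep(4L, n), ch)
  out <- clean_record(rec, preprocess_config(edge_trim_s = 35))
  expect_equal(nrow(out$channels), 1000L) # (80 - 70) s * 100 Hz
  expect_false(anyNA(out$channels))

  # all-zero channel with one missing sample: repaired to the mean, 0
  ch2 <- cbind(rep(0, n), rnorm(n))
  ch2[4000, 1] <- NA
  rec2 <- hap_recording((seq_len(n) - 1) / fs, rep(4L, n), ch2)
  out2 <- clean_record(rec2, preprocess_config(edge_trim_s = 35))
  expect_equal(out2$channels[4000 - 3500, 1], 0)

  # unit-variance noise with one wild sample: z-score flags it and the
  # replacement equals the mean of the unflagged samples
  set.seed(2)
  x <- rnorm(n)
  x[4200] <- 100
  rec3 <- hap_recording((seq_len(n) - 1) / fs, rep(4L, n),
                        cbind(x, rnorm(n)))
  out3 <- clean_record(rec3, preprocess_config(edge_trim_s = 35,
                                               outlier_zscore = 4))
  kept <- x[3501:(n - 3500)]
  mu0 <- mean(kept)
  s0 <- sd(kept)
  flagged <- abs(kept - mu0) > 4 * s0
  expect_true(flagged[700]) # the wild sample, at offset 4200 - 3500
  expect_equal(unname(out3$channels[700, 1]), mean(kept[!flagged]),
               tolerance = 1e-12)

  short <- hap_recording((1:50) / fs, rep(4L, 50), ch[1:50, ])
  expect_error(clean_record(short, preprocess_config(edge_trim_s = 35)),
               "too short")
})

test_that("low-pass filter passes 5 Hz, attenuates 30 Hz, and is zero-phase for DC", {
  fs <- 100
  t <- (0:1999) / fs
  const <- matrix(1, length(t), 1)
  expect_equal(lowpass_filter(const, 15, fs), const, tolerance = 1e-6)
  s5 <- sin(2 * pi * 5 * t)
  s30 <- sin(2 * pi * 30 * t)
  y5 <- lowpass_filter(s5, 15, fs)
  y30 <- lowpass_filter(s30, 15, fs)
  expect_gte(fft_amplitude(y5, 5, fs), 0.95)
  expect_lte(fft_amplitude(y30, 30, fs), 0.10)
  expect_error(lowpass_filter(s5, 60, fs), "cutoff")
  expect_error(lowpass_filter(s5[1:10], 15, fs), "too short")
})

test_that("normalization removes means and bounds output in [-1, 1]", {
  expect_equal(normalize_global(matrix(c(-2, 0, 2), 3, 1)),
               matrix(c(-1, 0, 1), 3, 1))
  # shared global divisor across channels
  x <- cbind(A = c(-2, 0, 2), B = c(-1, 0, 1))
  y <- normalize_global(x)
  expect_equal(unname(y[, 1]), c(-1, 0, 1))
  expect_equal(unname(y[, 2]), c(-0.5, 0, 0.5))
  # constant channel maps to zeros
  y2 <- normalize_global(cbind(c(5, 5, 5), c(0, 1, 2)))
  expect_equal(unname(y2[, 1]), c(0, 0, 0))
  expect_warning(normalize_global(matrix(1, 4, 2)), "constant")
  # per-channel mode scales each channel to full range
  y3 <- normalize_global(x, scope = "per_channel")
  expect_equal(unname(y3[, 2]), c(-1, 0, 1))
  set.seed(3)
  r <- normalize_global(matrix(rnorm(300, sd = 10), 100, 3))
  expect_true(all(r >= -1 & r <= 1))
})

test_that("re-normalizing a normalized signal changes nothing", {
  set.seed(9)
  x <- matrix(rnorm(600, mean = 3, sd = 4), 100, 6)
  y <- normalize_global(x)
  expect_equal(normalize_global(y), y, tolerance = 1e-12)
})

test_that("moving average smooths with shrinking edge windows", {
  const <- matrix(2, 50, 2)
  expect_equal(smooth_moving_average(const, 5), const)
  # unit impulse spreads into five values of 1/5
  x <- rep(0, 101)
  x[51] <- 1
  y <- smooth_moving_average(x, 5)
  expect_equal(y[49:53], rep(0.2, 5))
  expect_equal(sum(y != 0), 5L)
  # linear ramp: symmetric windows leave interior values unchanged
  r <- seq_len(40)
  yr <- smooth_moving_average(r, 5)
  expect_equal(yr[3:38], as.numeric(r[3:38]))
  expect_equal(length(yr), 40L)
  expect_error(smooth_moving_average(1:10, 4), "odd")
  expect_error(smooth_moving_average(1:3, 5), "larger")
})

test_that("segmentation obeys the closed-form window count", {
  cfg <- preprocess_config(epoch_s = 5.12, window_stride = 512L)
  m <- matrix(rnorm(1024 * 6), 1024, 6)
  expect_equal(length(segment_epochs(m, cfg, label = "walk")), 2L)
  cfg2 <- preprocess_config(window_stride = 256L)
  expect_equal(length(segment_epochs(m, cfg2, label = "walk")), 3L)
  expect_equal(length(segment_epochs(m[1:511, ], cfg2, label = "walk")), 0L)
  # randomized L, W, S against floor((L - W)/S) + 1
  set.seed(21)
  for (k in 1:20) {
    W <- sample(c(64L, 128L, 256L), 1)
    S <- sample(c(32L, 64L, 128L, 256L), 1)
    L <- W + sample(0:1000, 1)
    cfgk <- preprocess_config(epoch_s = W / 100, window_stride = S)
    n <- length(segment_epochs(matrix(0, L, 2), cfgk, label = "walk"))
    expect_equal(n, (L - W) %/% S + 1L)
  }
})

test_that("epochs split into exactly reconstructable halves", {
  ep <- matrix(seq_len(512 * 6), 512, 6)
  ep[, 1] <- 0:511
  pr <- split_epoch(ep)
  expect_equal(dim(pr$observed), c(256L, 6L))
  expect_equal(dim(pr$future), c(256L, 6L))
  expect_equal(pr$observed[256, 1], 255)
  expect_equal(pr$future[1, 1], 256)
  expect_equal(rbind(pr$observed, pr$future), ep)
  expect_error(split_epoch(ep[1:511, ]), "even")
})

test_that("make_pairs mirrors split_epoch over a whole epoch set", {
  set.seed(4)
  eps <- hap_epochs(lapply(1:3, function(i) matrix(rnorm(64 * 2), 64, 2)),
                    label = c("walk", "run", "walk"))
  pairs <- make_pairs(eps)
  expect_equal(length(pairs), 3L)
  expect_equal(dim(pairs$observed), c(3L, 32L, 2L))
  for (i in 1:3) {
    full <- rbind(pairs$observed[i, , ], pairs$future[i, , ])
    expect_equal(full, epoch_matrix(eps, i))
  }
})
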
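make_pamap2_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".dat",
                                .local_envir = parent.frame())
  writeLines(vapply(rows, paste, "", collapse = " "), path)
  path
}

toy_row <- function(ts, act, chest = c(1, 2, 3), ankle = c(4, 5, 6)) {
  r <- rep("0", 54)
  r[1] <- format(ts)
  r[2] <- format(act)
  r[3] <- "NaN"
  r[22:24] <- format(chest)
  r[39:41] <- format(ankle)
  r
}

test_that("reader extracts the six accelerometer channels in fixed order", {
  path <- make_pamap2_file(list(toy_row(0.00, 4), toy_row(0.01, 4),
                                toy_row(0.02, 5, chest = c(7, 8, 9))))
  rec <- read_pamap2(path)
  expect_s3_class(rec, "hap_recording")
  expect_equal(dim(rec$channels), c(3L, 6L))
  expect_equal(colnames(rec$channels),
               c("chest_x", "chest_y", "chest_z",
                 "ankle_x", "ankle_y", "ankle_z"))
  expect_equal(unname(rec$channels[1, ]), c(1, 2, 3, 4, 5, 6))
  expect_equal(unname(rec$channels[3, 1:3]), c(7, 8, 9))
  expect_equal(rec$activity_id, c(4L, 4L, 5L))
  # row count in = row count out
  expect_equal(nrow(rec$channels), 3L)
})

test_that("reader maps NaN tokens to the missing sentinel and flags bad rows", {
  row2 <- toy_row(0.01, 4)
  row2[22] <- "NaN"
  path <- make_pamap2_file(list(toy_row(0, 4), row2))
  rec <- read_pamap2(path)
  expect_true(is.na(rec$channels[2, 1]))
  expect_equal(unname(rec$channels[2, 2]), 2)

  bad <- make_pamap2_file(list(toy_row(0, 4), rep("1", 10)))
  expect_error(read_pamap2(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".dat")
  file.create(empty)
  expect_error(read_pamap2(empty), "empty")
  expect_error(read_pamap2(file.path(tempdir(), "no-such-file.dat")),
               "not found")
})

test_that("write_pamap2 round-trips through the reader", {
  set.seed(8)
  ch <- matrix(round(rnorm(60), 6), 10, 6)
  ch[3, 2] <- NA
  rec <- hap_recording((0:9) / 100, rep(4L, 10), ch, subject_id = "s1")
  path <- withr::local_tempfile(fileext = ".dat")
  write_pamap2(rec, path)
  back <- read_pamap2(path, subject_id = "s1")
  expect_equal(unname(back$channels), unname(ch), tolerance = 1e-9)
  expect_equal(back$activity_id, rec$activity_id)
})

test_that("activity filtering keeps contiguous runs as separate segments", {
  ch <- matrix(seq_len(10), 5, 2)
  rec <- hap_recording((0:4) / 100, c(4L, 4L, 5L, 5L, 4L), ch)
  segs <- filter_by_activity(rec, "walk")
  expect_length(segs, 2L)
  expect_equal(nrow(segs[[1]]$channels), 2L)
  expect_equal(nrow(segs[[2]]$channels), 1L)
  expect_equal(attr(segs[[1]], "activity"), "walk")
  # absent activity: zero segments, no error
  expect_length(filter_by_activity(rec, "nordic_walk"), 0L)
  expect_error(filter_by_activity(rec, "jog"), "valid labels")
})

test_that("retained samples equal the count of in-set activity IDs", {
  set.seed(12)
  ids <- sample(c(4L, 5L, 7L, 12L, 13L, 1L, 0L), 500, replace = TRUE)
  rec <- hap_recording((seq_len(500) - 1) / 100, ids,
                       matrix(rnorm(1000), 500, 2))
  segs <- filter_by_activity(rec, hap_activities())
  kept <- sum(vapply(segs, function(s) nrow(s$channels), 1L))
  expect_equal(kept, sum(ids %in% pamap2_activity_codes()))
})

test_that("epoch container round trip is exact", {
  set.seed(10)
  eps <- hap_epochs(lapply(1:10, function(i) matrix(rnorm(32 * 6), 32, 6)),
                    label = sample(hap_activities(), 10, replace = TRUE),
                    subject_id = "s7")
  path <- withr::local_tempfile(fileext = ".rds")
  save_epochs(eps, path)
  back <- load_epochs(path)
  expect_identical(back$data, eps$data)
  expect_identical(back$label, eps$label)
  expect_identical(back$subject_id, eps$subject_id)
  # empty set round trip
  e0 <- hap_epochs(list(), character(0))
  save_epochs(e0, path)
  expect_equal(length(load_epochs(path)), 0L)
  expect_error(load_epochs(file.path(tempdir(), "missing.rds")), "not found")
  txt <- withr::local_tempfile(fileext = ".rds")
  writeLines("not an epoch container", txt)
  expect_error(load_epochs(txt), "corrupt")
})

test_that("epoch sets subset and combine consistently", {
  eps <- hap_epochs(lapply(1:4, function(i) matrix(i, 8, 2)),
                    label = c("walk", "run", "walk", "run"))
  sub <- eps[c(1, 3)]
  expect_equal(length(sub), 2L)
  expect_equal(sub$label, c("walk", "walk"))
  both <- c(eps[1:2], eps[3:4])
  expect_equal(length(both), 4L)
  expect_equal(both$label, eps$label)
  expect_equal(epoch_matrix(both, 4), matrix(4, 8, 2))
})
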
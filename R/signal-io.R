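# Containers and I/O for raw recordings and epoch datasets.

#' The five activity labels handled by the pipeline
#' @return character vector of activity labels.
#' @export
hap_activities <- function() {
  c("walk", "run", "nordic_walk", "stairs_ascend", "stairs_descend")
}

#' PAMAP2 activity-label to integer-ID mapping
#'
#' The dataset's documented codes for the five activities used here. The
#' mapping is data, not code: synthetic recordings may use arbitrary codes by
#' passing their own mapping to [filter_by_activity()].
#' @return named integer vector (names are labels, values are activity IDs).
#' @export
pamap2_activity_codes <- function() {
  c(walk = 4L, run = 5L, nordic_walk = 7L,
    stairs_ascend = 12L, stairs_descend = 13L)
}

#' Default PAMAP2 channel selection: chest and ankle +-16 g accelerometers
#'
#' 1-based column indices into the 54-column PAMAP2 row layout (timestamp,
#' activity ID, heart rate, then 17 columns per IMU for hand, chest, ankle).
#' Order is fixed: chest x/y/z then ankle x/y/z.
#' @return named integer vector of column indices.
#' @export
pamap2_channels <- function() {
  c(chest_x = 22L, chest_y = 23L, chest_z = 24L,
    ankle_x = 39L, ankle_y = 40L, ankle_z = 41L)
}

#' Construct a raw recording object
#'
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing at the nominal sampling rate.
#' @param activity_id integer activity code per sample.
#' @param channels numeric matrix, samples x channels (may contain `NA`
#'   missing-value sentinels before preprocessing).
#' @param subject_id subject identifier string.
#' @param sampling_rate sampling rate in Hz (default 100).
#' @return an object of class `hap_recording`.
#' @export
hap_recording <- function(timestamps, activity_id, channels,
                          subject_id = "synthetic", sampling_rate = 100) {
  channels <- as.matrix(channels)
  stopifnot(length(timestamps) == nrow(channels),
            length(activity_id) == nrow(channels))
  if (nrow(channels) > 1 && any(diff(timestamps) <= 0))
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  structure(list(
    timestamps = as.numeric(timestamps),
    activity_id = as.integer(activity_id),
    channels = channels,
    subject_id = subject_id,
    sampling_rate = sampling_rate
  ), class = "hap_recording")
}

#' @export
print.hap_recording <- function(x, ...) {
  cat("<hap_recording> subject", x$subject_id, "-",
      nrow(x$channels), "samples x", ncol(x$channels), "channels @",
      x$sampling_rate, "Hz (", round(nrow(x$channels) / x$sampling_rate, 2),
      "s )\n")
  invisible(x)
}

#' @export
as_tibble.hap_recording <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$channels)) |>
    dplyr::mutate(time_s = x$timestamps, activity_id = x$activity_id,
                  subject_id = x$subject_id, .before = 1)
}

#' Read a PAMAP2-format raw recording
#'
#' Parses whitespace-separated text with one 54-column row per 100 Hz sample
#' and extracts the requested accelerometer channels (default: chest and
#' ankle +-16 g tri-axial, six channels in fixed chest-x/y/z, ankle-x/y/z
#' order). The PAMAP2 missing-value token `NaN` (or an `NA` field) becomes
#' the `NA` sentinel; no rows are dropped.
#'
#' @param path path to the `.dat` file.
#' @param channels named integer vector of 1-based column indices to keep
#'   (default [pamap2_channels()]).
#' @param subject_id subject identifier recorded on the result; defaults to
#'   the file name without extension.
#' @param sampling_rate sampling rate in Hz (default 100).
#' @param n_columns expected row width (default 54).
#' @return a [hap_recording()].
#' @export
read_pamap2 <- function(path, channels = pamap2_channels(),
                        subject_id = NULL, sampling_rate = 100,
                        n_columns = 54L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  widths <- utils::count.fields(path, blank.lines.skip = TRUE)
  if (length(widths) == 0) stop("empty PAMAP2 file: ", path, call. = FALSE)
  bad <- which(widths != n_columns)
  if (length(bad) > 0)
    stop("malformed PAMAP2 row: line ", bad[1L], " has ", widths[bad[1L]],
         " fields, expected ", n_columns, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE,
                           na.strings = c("NaN", "NA"),
                           colClasses = "numeric")
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  ch <- as.matrix(raw[, channels, drop = FALSE])
  colnames(ch) <- names(channels)
  act <- raw[[2L]]
  act[is.na(act)] <- 0L
  hap_recording(timestamps = raw[[1L]], activity_id = act, channels = ch,
                subject_id = subject_id, sampling_rate = sampling_rate)
}

#' Write a recording as PAMAP2-format text
#'
#' Emits the 54-column whitespace-separated layout with the recording's
#' channels placed at the given column indices, so the reader can be
#' exercised end-to-end on simulated data. Unused columns are zero; missing
#' values are written as `NaN`.
#'
#' @param rec a [hap_recording()].
#' @param path output file path.
#' @param channels column placement (default [pamap2_channels()]).
#' @param n_columns row width (default 54).
#' @return `path`, invisibly.
#' @export
write_pamap2 <- function(rec, path, channels = pamap2_channels(),
                         n_columns = 54L) {
  n <- nrow(rec$channels)
  M <- matrix(0, n, n_columns)
  M[, 1L] <- rec$timestamps
  M[, 2L] <- rec$activity_id
  M[, 3L] <- NaN # heart rate, unused
  for (j in seq_along(channels)) M[, channels[j]] <- rec$channels[, j]
  M[is.na(M)] <- NaN
  lines <- apply(M, 1L, function(r) paste(format(r, trim = TRUE,
                                                 digits = 10), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Keep only contiguous runs of the requested activities
#'
#' Splits a recording into per-activity contiguous segments, preserving
#' temporal order, and keeps those whose activity is in `activities`.
#'
#' @param rec a [hap_recording()].
#' @param activities character vector of activity labels to keep.
#' @param codes named integer label-to-ID mapping
#'   (default [pamap2_activity_codes()]).
#' @return a list of `hap_recording` segments, each with an `"activity"`
#'   attribute carrying its label; zero-length if no run matches.
#' @export
filter_by_activity <- function(rec, activities,
                               codes = pamap2_activity_codes()) {
  unknown <- setdiff(activities, names(codes))
  if (length(unknown) > 0)
    stop("unknown activity label(s): ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(names(codes), collapse = ", "),
         call. = FALSE)
  keep_ids <- codes[activities]
  r <- rle(rec$activity_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in seq_along(r$values)) {
    if (!(r$values[k] %in% keep_ids)) next
    idx <- starts[k]:ends[k]
    seg <- hap_recording(rec$timestamps[idx], rec$activity_id[idx],
                         rec$channels[idx, , drop = FALSE],
                         rec$subject_id, rec$sampling_rate)
    attr(seg, "activity") <- names(codes)[match(r$values[k], codes)]
    segs[[length(segs) + 1L]] <- seg
  }
  segs
}

# ---- epoch container --------------------------------------------------------

#' Construct an epoch set
#'
#' A set of fixed-length preprocessed signal windows with labels. Data is a
#' 3-D array `(n_epochs, epoch_len, n_channels)`; after preprocessing all
#' values are finite and within `[-1, 1]`.
#'
#' @param data 3-D numeric array `(n, len, channels)`, or a list of
#'   `len x channels` matrices.
#' @param label character vector of activity labels, length `n`.
#' @param subject_id character vector (recycled) of subject IDs.
#' @return an object of class `hap_epochs`.
#' @export
hap_epochs <- function(data, label, subject_id = "synthetic") {
  if (is.list(data)) {
    if (length(data) == 0) {
      data <- array(numeric(0), c(0L, 0L, 0L))
    } else {
      data <- aperm(simplify2array(data), c(3L, 1L, 2L))
    }
  }
  n <- dim(data)[1L]
  stopifnot(length(label) == n)
  subject_id <- rep_len(as.character(subject_id), n)
  structure(list(data = data, label = as.character(label),
                 subject_id = subject_id),
            class = "hap_epochs")
}

#' @export
length.hap_epochs <- function(x) dim(x$data)[1L]

#' @export
print.hap_epochs <- function(x, ...) {
  cat("<hap_epochs>", length(x), "epochs of", dim(x$data)[2L], "x",
      dim(x$data)[3L], "\n")
  if (length(x) > 0) print(table(x$label))
  invisible(x)
}

#' Extract one epoch's data matrix
#' @param x a [hap_epochs()] set.
#' @param i epoch index.
#' @return `len x channels` matrix.
#' @export
epoch_matrix <- function(x, i) {
  stopifnot(inherits(x, "hap_epochs"), i >= 1, i <= length(x))
  m <- x$data[i, , ]
  dim(m) <- dim(x$data)[2:3]
  m
}

#' Subset an epoch set
#' @param x a [hap_epochs()] set.
#' @param i index vector.
#' @param ... unused.
#' @return a `hap_epochs` subset.
#' @export
`[.hap_epochs` <- function(x, i, ...) {
  hap_epochs(x$data[i, , , drop = FALSE], x$label[i], x$subject_id[i])
}

#' Combine epoch sets
#' @param ... `hap_epochs` objects with identical epoch shape.
#' @return a single `hap_epochs`.
#' @export
c.hap_epochs <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, length, 1L) > 0]
  if (length(xs) == 0) return(hap_epochs(list(), character(0)))
  data <- do.call(abind1, lapply(xs, `[[`, "data"))
  hap_epochs(data, unlist(lapply(xs, `[[`, "label")),
             unlist(lapply(xs, `[[`, "subject_id")))
}

# bind 3-D arrays along the first margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])[2:3]
  n <- sum(vapply(arrs, function(a) dim(a)[1L], 1L))
  out <- array(0, c(n, d))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0) out[(at + 1L):(at + k), , ] <- a
    at <- at + k
  }
  out
}

#' Save / load an epoch set
#'
#' The container is R's native serialized format, giving a bit-exact round
#' trip for data, labels and subject IDs.
#'
#' @param epochs a [hap_epochs()] set.
#' @param path file path.
#' @return `save_epochs()` returns `path` invisibly; `load_epochs()` returns
#'   the `hap_epochs` object.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "hap_epochs"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt epoch container: ",
                                           conditionMessage(e), call. = FALSE))
  if (!inherits(out, "hap_epochs"))
    stop("file does not contain an epoch set", call. = FALSE)
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
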
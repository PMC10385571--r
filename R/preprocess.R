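# Preprocessing stack: clean -> low-pass -> normalize -> smooth -> segment.

#' Preprocessing configuration
#'
#' @param edge_trim_s seconds trimmed from each end of a recording
#'   (default 35).
#' @param lowpass_cutoff_hz low-pass cutoff in Hz (default 15).
#' @param filter_order Butterworth filter order (default 4; applied
#'   forward-backward, so zero phase).
#' @param ma_window moving-average window in samples (odd, default 5).
#' @param epoch_s epoch length in seconds (default 5.12, i.e. 512 samples at
#'   100 Hz); `epoch_s * fs` must be an even integer so halves split exactly.
#' @param window_stride sliding-window stride in samples (default 256,
#'   i.e. 50 percent overlap).
#' @param outlier_zscore per-channel z-score beyond which a sample is
#'   treated as an outlier artifact (default 4).
#' @param normalization `"global"` (per-channel mean removal, then one
#'   shared max-abs divisor across channels) or `"per_channel"`.
#' @return an object of class `hap_preprocess_config`.
#' @export
preprocess_config <- function(edge_trim_s = 35, lowpass_cutoff_hz = 15,
                              filter_order = 4L, ma_window = 5L,
                              epoch_s = 5.12, window_stride = 256L,
                              outlier_zscore = 4,
                              normalization = c("global", "per_channel")) {
  normalization <- match.arg(normalization)
  if (ma_window < 1L || ma_window %% 2L == 0L)
    stop("`ma_window` must be odd and >= 1", call. = FALSE)
  structure(list(edge_trim_s = edge_trim_s,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 filter_order = as.integer(filter_order),
                 ma_window = as.integer(ma_window),
                 epoch_s = epoch_s,
                 window_stride = as.integer(window_stride),
                 outlier_zscore = outlier_zscore,
                 normalization = normalization),
            class = "hap_preprocess_config")
}

epoch_samples <- function(cfg, fs) {
  W <- cfg$epoch_s * fs
  if (abs(W - round(W)) > 1e-9 || round(W) %% 2L != 0L)
    stop("`epoch_s * fs` must be an even integer of samples", call. = FALSE)
  as.integer(round(W))
}

#' Trim recording edges and repair missing/outlier samples
#'
#' Removes the first and last `edge_trim_s` seconds, then replaces every
#' missing sample and every sample whose per-channel z-score exceeds
#' `outlier_zscore` with that channel's mean over the retained segment
#' (computed excluding the flagged samples). The output contains no missing
#' values.
#'
#' @param rec a [hap_recording()].
#' @param cfg a [preprocess_config()].
#' @return a cleaned `hap_recording`.
#' @export
clean_record <- function(rec, cfg = preprocess_config()) {
  fs <- rec$sampling_rate
  n <- nrow(rec$channels)
  n_trim <- as.integer(round(cfg$edge_trim_s * fs))
  if (n <= 2L * n_trim)
    stop("record too short after edge trim (", n / fs, " s <= ",
         2 * cfg$edge_trim_s, " s)", call. = FALSE)
  idx <- (n_trim + 1L):(n - n_trim)
  ch <- rec$channels[idx, , drop = FALSE]
  for (j in seq_len(ncol(ch))) {
    x <- ch[, j]
    miss <- !is.finite(x)
    mu0 <- mean(x[!miss])
    s0 <- stats::sd(x[!miss])
    out <- if (is.finite(s0) && s0 > 0) {
      !miss & abs(x - mu0) > cfg$outlier_zscore * s0
    } else rep(FALSE, length(x))
    bad <- miss | out
    repl <- if (all(bad)) 0 else mean(x[!bad])
    x[bad] <- repl
    ch[, j] <- x
  }
  hap_recording(rec$timestamps[idx], rec$activity_id[idx], ch,
                rec$subject_id, fs)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (`signal::filtfilt`), so the passband is preserved with near-unity gain
#' and no phase lag that would misalign forecast targets.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz; must exceed `2 * cutoff_hz`.
#' @param order filter order (default 4).
#' @return filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz, fs, order = 4L) {
  if (fs <= 2 * cutoff_hz)
    stop("`fs` must exceed twice the cutoff frequency", call. = FALSE)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # reflective (odd) padding plus an explicit forward-backward pass
  # suppresses the startup transients of zero-state filtering at both ends
  pad <- 12L * (max(length(bf$b), length(bf$a)) - 1L)
  if (nrow(X) <= pad)
    stop("signal too short for zero-phase filtering (need > ", pad,
         " samples)", call. = FALSE)
  n <- nrow(X)
  Y <- apply(X, 2L, function(col) {
    head_pad <- 2 * col[1L] - col[(pad + 1L):2L]
    tail_pad <- 2 * col[n] - col[(n - 1L):(n - pad)]
    z <- as.numeric(signal::filter(bf, c(head_pad, col, tail_pad)))
    z <- rev(as.numeric(signal::filter(bf, rev(z))))
    z[(pad + 1L):(pad + n)]
  })
  dimnames(Y) <- dimnames(X)
  if (vec) as.numeric(Y) else Y
}

#' Mean removal and global normalization to [-1, 1]
#'
#' Subtracts each channel's mean, then divides all channels by a shared
#' divisor: the single maximum absolute value across all channels
#' (`scope = "global"`, the default) or each channel's own maximum
#' (`scope = "per_channel"`). An all-constant channel maps to zeros; an
#' entirely constant input returns zeros with a warning.
#'
#' @param x numeric matrix (samples x channels).
#' @param scope `"global"` or `"per_channel"`.
#' @return matrix of the same shape with values in `[-1, 1]`.
#' @export
normalize_global <- function(x, scope = c("global", "per_channel")) {
  scope <- match.arg(scope)
  X <- as.matrix(x)
  X <- sweep(X, 2L, colMeans(X), "-")
  if (scope == "global") {
    m <- max(abs(X))
    if (m == 0) {
      warning("entirely constant input; returning zeros", call. = FALSE)
      return(X)
    }
    X <- X / m
  } else {
    m <- apply(abs(X), 2L, max)
    if (all(m == 0)) {
      warning("entirely constant input; returning zeros", call. = FALSE)
      return(X)
    }
    m[m == 0] <- 1
    X <- sweep(X, 2L, m, "/")
  }
  X
}

#' Centered moving-average smoothing
#'
#' Per-channel centered moving mean; edges use shrinking windows so the
#' output length equals the input length.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param window odd window width in samples (default 5).
#' @return smoothed signal, same shape as `x`.
#' @export
smooth_moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be odd and >= 1", call. = FALSE)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  n <- nrow(X)
  if (window > n) stop("`window` larger than signal length", call. = FALSE)
  h <- window %/% 2L
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  Y <- apply(X, 2L, function(col) {
    cs <- cumsum(c(0, col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  Y <- matrix(Y, nrow = n, dimnames = dimnames(X))
  if (vec) as.numeric(Y) else Y
}

#' Segment a single-activity recording into overlapping epochs
#'
#' Takes sliding windows of `epoch_s * fs` samples at stride
#' `window_stride`; each window becomes one epoch carrying the segment's
#' activity label. A trailing remainder shorter than a window is discarded,
#' so the number of epochs is `floor((L - W) / S) + 1` for `L >= W`, else 0.
#'
#' @param segment a preprocessed single-activity [hap_recording()] (as
#'   produced by [filter_by_activity()]), or a plain samples x channels
#'   matrix.
#' @param cfg a [preprocess_config()].
#' @param label activity label for the epochs; defaults to the segment's
#'   `"activity"` attribute.
#' @param fs sampling rate; defaults to the recording's.
#' @param subject_id subject ID; defaults to the recording's.
#' @return a [hap_epochs()] set (possibly empty).
#' @export
segment_epochs <- function(segment, cfg = preprocess_config(), label = NULL,
                           fs = NULL, subject_id = NULL) {
  if (inherits(segment, "hap_recording")) {
    if (is.null(label)) label <- attr(segment, "activity")
    if (is.null(fs)) fs <- segment$sampling_rate
    if (is.null(subject_id)) subject_id <- segment$subject_id
    X <- segment$channels
  } else {
    X <- as.matrix(segment)
    if (is.null(fs)) fs <- 100
    if (is.null(subject_id)) subject_id <- "synthetic"
  }
  if (is.null(label)) label <- "unknown"
  W <- epoch_samples(cfg, fs)
  S <- cfg$window_stride
  L <- nrow(X)
  if (L < W) return(hap_epochs(list(), character(0)))
  n_win <- (L - W) %/% S + 1L
  wins <- lapply(seq_len(n_win), function(k) {
    X[((k - 1L) * S + 1L):((k - 1L) * S + W), , drop = FALSE]
  })
  hap_epochs(wins, rep(label, n_win), subject_id)
}

#' Split an epoch into observed and future halves
#'
#' 0-based half-open convention: observed = samples `[0, n/2)`, future =
#' samples `[n/2, n)`. Concatenating the halves reconstructs the epoch
#' exactly.
#'
#' @param epoch a `len x channels` matrix with an even number of rows.
#' @return a list with `observed` and `future` matrices of equal shape.
#' @export
split_epoch <- function(epoch) {
  epoch <- as.matrix(epoch)
  n <- nrow(epoch)
  if (n %% 2L != 0L) stop("epoch length must be even", call. = FALSE)
  half <- n %/% 2L
  list(observed = epoch[seq_len(half), , drop = FALSE],
       future = epoch[(half + 1L):n, , drop = FALSE])
}

#' Build forecaster input/target pairs from an epoch set
#'
#' @param epochs a [hap_epochs()] set with even epoch length.
#' @return an object of class `hap_pairs`: list with `observed` and `future`
#'   arrays `(n, len/2, channels)` and `label`.
#' @export
make_pairs <- function(epochs) {
  stopifnot(inherits(epochs, "hap_epochs"))
  len <- dim(epochs$data)[2L]
  if (len %% 2L != 0L) stop("epoch length must be even", call. = FALSE)
  half <- len %/% 2L
  structure(list(
    observed = epochs$data[, seq_len(half), , drop = FALSE],
    future = epochs$data[, (half + 1L):len, , drop = FALSE],
    label = epochs$label
  ), class = "hap_pairs")
}

#' @export
length.hap_pairs <- function(x) dim(x$observed)[1L]

#' @export
print.hap_pairs <- function(x, ...) {
  cat("<hap_pairs>", length(x), "pairs of", dim(x$observed)[2L], "x",
      dim(x$observed)[3L], "(observed | future)\n")
  invisible(x)
}

#' Run the full preprocessing stack on a raw recording
#'
#' Applies, in order: edge trim + artifact repair ([clean_record()]),
#' zero-phase low-pass ([lowpass_filter()]), mean removal and normalization
#' ([normalize_global()]), moving-average smoothing
#' ([smooth_moving_average()]), activity filtering
#' ([filter_by_activity()]) and sliding-window segmentation
#' ([segment_epochs()]).
#'
#' @param rec a raw [hap_recording()].
#' @param cfg a [preprocess_config()].
#' @param activities labels to keep (default all five).
#' @param codes label-to-ID mapping.
#' @return a [hap_epochs()] set pooling all activity segments.
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config(),
                                 activities = hap_activities(),
                                 codes = pamap2_activity_codes()) {
  rec <- clean_record(rec, cfg)
  ch <- lowpass_filter(rec$channels, cfg$lowpass_cutoff_hz,
                       rec$sampling_rate, cfg$filter_order)
  ch <- normalize_global(ch, cfg$normalization)
  ch <- smooth_moving_average(ch, cfg$ma_window)
  rec$channels <- ch
  segs <- filter_by_activity(rec, activities, codes)
  eps <- lapply(segs, segment_epochs, cfg = cfg)
  if (length(eps) == 0) return(hap_epochs(list(), character(0)))
  do.call(c, eps)
}
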
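#' Root-mean-square error between measured and forecasted signals
#'
#' `sqrt(mean((y - yhat)^2))`. For matrix input (samples x channels) the
#' per-channel RMSE values and their mean are returned.
#'
#' @param y ground-truth vector or matrix.
#' @param yhat forecast of the same shape.
#' @return for vectors, a scalar; for matrices, a list with `per_channel`
#'   (named numeric vector) and `mean`.
#' @examples
#' rmse(c(1, 2, 3), c(2, 3, 4))
#' @export
rmse <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("`y` and `yhat` must have identical shape", call. = FALSE)
  if (is.matrix(y)) {
    per <- sqrt(colMeans((y - yhat)^2))
    if (is.null(names(per))) names(per) <- paste0("ch", seq_along(per))
    return(list(per_channel = per, mean = mean(per)))
  }
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation between measured and forecasted signals
#'
#' The linear correlation coefficient in `[-1, 1]`; +/-1 indicates a perfect
#' (anti)correlated forecast. Zero-variance input is an error rather than a
#' silent zero, because the coefficient is undefined there.
#'
#' @inheritParams rmse
#' @return for vectors, a scalar; for matrices, a list with `per_channel`
#'   and `mean`.
#' @examples
#' pearson_corr(1:10, 2 * (1:10) + 3)
#' @export
pearson_corr <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("`y` and `yhat` must have identical shape", call. = FALSE)
  one <- function(a, b) {
    da <- a - mean(a)
    db <- b - mean(b)
    va <- sum(da^2)
    vb <- sum(db^2)
    if (va == 0 || vb == 0)
      stop("correlation undefined for zero-variance input", call. = FALSE)
    sum(da * db) / sqrt(va * vb)
  }
  if (is.matrix(y)) {
    per <- vapply(seq_len(ncol(y)), function(j) one(y[, j], yhat[, j]),
                  numeric(1))
    names(per) <- if (!is.null(colnames(y))) colnames(y)
                  else paste0("ch", seq_len(ncol(y)))
    return(list(per_channel = per, mean = mean(per)))
  }
  one(as.numeric(y), as.numeric(yhat))
}

#' Classification report with one-vs-rest accuracy, precision and F1
#'
#' Builds the confusion matrix (rows = true, columns = predicted) and, for
#' each class treated one-vs-rest, the counts Tp/Tn/Fp/Fn and the derived
#' metrics: accuracy `(Tp+Tn)/(Tp+Tn+Fp+Fn)`, precision `Tp/(Tp+Fp)` and
#' F1 `Tp/(Tp + (Fp+Fn)/2)`. Macro averages are the plain means over
#' classes; `accuracy_overall` is the fraction of exactly correct labels.
#'
#' @param truth integer or factor vector of true class labels.
#' @param predicted vector of predicted labels, same length and coding.
#' @param labels optional vector of all class labels (defaults to the sorted
#'   union of `truth` and `predicted`).
#' @return an object of class `hap_classification_report`: a list with
#'   `confusion` (matrix), `per_class` (tibble), `accuracy_overall`,
#'   `accuracy_macro`, `precision_macro`, `f1_macro` and `n`.
#' @export
classification_report <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  labels <- as.character(labels)
  bad <- setdiff(unique(c(truth, predicted)), labels)
  if (length(bad) > 0)
    stop("labels not in `labels`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tf <- factor(truth, levels = labels)
  pf <- factor(predicted, levels = labels)
  confusion <- table(truth = tf, predicted = pf)
  confusion <- matrix(as.integer(confusion), nrow = length(labels),
                      dimnames = list(truth = labels, predicted = labels))
  n <- length(truth)
  per <- purrr::map_dfr(seq_along(labels), function(k) {
    tp <- confusion[k, k]
    fp <- sum(confusion[-k, k])
    fn <- sum(confusion[k, -k])
    tn <- n - tp - fp - fn
    tibble::tibble(
      class = labels[k], tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = (tp + tn) / n,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) tp / (tp + (fp + fn) / 2) else NA_real_
    )
  })
  structure(list(
    confusion = confusion,
    per_class = per,
    accuracy_overall = sum(diag(confusion)) / n,
    accuracy_macro = mean(per$accuracy),
    precision_macro = mean(per$precision, na.rm = TRUE),
    f1_macro = mean(per$f1, na.rm = TRUE),
    n = n
  ), class = "hap_classification_report")
}

#' @export
print.hap_classification_report <- function(x, ...) {
  cat("Classification report (", x$n, " samples)\n", sep = "")
  cat("overall accuracy:", format(x$accuracy_overall, digits = 4),
      " macro precision:", format(x$precision_macro, digits = 4),
      " macro F1:", format(x$f1_macro, digits = 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Per-activity forecast metrics over a set of epoch pairs
#'
#' Evaluates a forecaster on a list of epoch pairs: per epoch, RMSE and
#' Pearson correlation are computed per channel and averaged; epochs are then
#' averaged within activity, the layout used for reporting forecast quality
#' per activity with a grand mean row.
#'
#' @param truths list of measured future halves (256 x 6 matrices).
#' @param forecasts list of forecasted halves, same shapes.
#' @param labels character/factor vector of activity labels per epoch.
#' @return a tibble with columns `activity`, `n_epochs`, `rmse`, `corr`,
#'   including a final `"mean"` row averaging over activities.
#' @export
forecast_metrics <- function(truths, forecasts, labels) {
  stopifnot(length(truths) == length(forecasts),
            length(truths) == length(labels))
  per_epoch <- tibble::tibble(
    activity = as.character(labels),
    rmse = purrr::map2_dbl(truths, forecasts, ~ rmse(.x, .y)$mean),
    corr = purrr::map2_dbl(truths, forecasts, ~ pearson_corr(.x, .y)$mean)
  )
  by_act <- per_epoch |>
    dplyr::group_by(.data$activity) |>
    dplyr::summarise(n_epochs = dplyr::n(), rmse = mean(.data$rmse),
                     corr = mean(.data$corr), .groups = "drop")
  dplyr::bind_rows(
    by_act,
    tibble::tibble(activity = "mean", n_epochs = sum(by_act$n_epochs),
                   rmse = mean(by_act$rmse), corr = mean(by_act$corr))
  )
}

#' @importFrom rlang .data
NULL
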
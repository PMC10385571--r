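# ggplot2 visualisations for forecasts, training histories and confusion
# matrices.

#' Plot an observed half, measured future and forecast per channel
#'
#' @param observed `input_len x channels` matrix fed to the forecaster.
#' @param future measured future half (may be `NULL`).
#' @param forecast forecasted half (may be `NULL`).
#' @param fs sampling rate in Hz used for the time axis (default 100).
#' @return a ggplot object, one facet per channel.
#' @export
plot_forecast <- function(observed, future = NULL, forecast = NULL,
                          fs = 100) {
  to_long <- function(m, what, t0) {
    if (is.null(colnames(m))) colnames(m) <- paste0("ch", seq_len(ncol(m)))
    tibble::as_tibble(as.data.frame(m)) |>
      dplyr::mutate(time_s = t0 + (dplyr::row_number() - 1) / fs,
                    signal = what) |>
      tidyr::pivot_longer(-c("time_s", "signal"), names_to = "channel",
                          values_to = "value")
  }
  t1 <- nrow(observed) / fs
  df <- dplyr::bind_rows(
    to_long(observed, "observed", 0),
    if (!is.null(future)) to_long(future, "measured future", t1),
    if (!is.null(forecast)) to_long(forecast, "forecast", t1)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                   colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = t1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~channel, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "normalized acceleration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hap_forecaster <- function(object, ...) {
  stopifnot(!is.null(object$history))
  ggplot2::ggplot(object$history, ggplot2::aes(.data$pass, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste("training loss -", object$spec$architecture),
                  x = "pass", y = "MSE (log scale)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hap_classifier <- function(object, ...) {
  stopifnot(!is.null(object$history))
  ggplot2::ggplot(object$history, ggplot2::aes(.data$pass, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "classifier training loss", x = "pass",
                  y = "cross-entropy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hap_classification_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @export
tidy.hap_classification_report <- function(x, ...) {
  x$per_class
}

#' @export
glance.hap_classification_report <- function(x, ...) {
  tibble::tibble(accuracy_overall = x$accuracy_overall,
                 accuracy_macro = x$accuracy_macro,
                 precision_macro = x$precision_macro,
                 f1_macro = x$f1_macro, n = x$n)
}
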
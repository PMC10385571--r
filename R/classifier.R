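# Bi-LSTM activity classifier: two bidirectional LSTM layers (the second
# returning only its final forward/backward states, concatenated), ReLU, a
# dense hidden layer, and a softmax head over the activity classes.

#' Classifier architecture specification
#'
#' Reference sizing: Bi-LSTM layers of 64 and 32 units, a 352-neuron hidden
#' layer and a 5-way softmax. Reduced sizes (e.g. `bilstm_units = c(16, 8)`,
#' `hidden_neurons = 64`) train in well under a minute per pass on one CPU.
#'
#' @param input_len samples per input window (default 256, the epoch half).
#' @param n_channels signal channels (default 6).
#' @param bilstm_units widths of the two bidirectional layers
#'   (default `c(64, 32)`).
#' @param hidden_neurons dense hidden layer width (default 352).
#' @param classes character vector of class labels
#'   (default [hap_activities()]).
#' @param seed seed for parameter initialisation.
#' @return an object of class `hap_classifier_spec`.
#' @export
classifier_spec <- function(input_len = 256L, n_channels = 6L,
                            bilstm_units = c(64L, 32L),
                            hidden_neurons = 352L,
                            classes = hap_activities(), seed = 1L) {
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  structure(list(input_len = as.integer(input_len),
                 n_channels = as.integer(n_channels),
                 bilstm_units = as.integer(bilstm_units),
                 hidden_neurons = as.integer(hidden_neurons),
                 classes = as.character(classes),
                 n_classes = length(classes),
                 seed = as.integer(seed)),
            class = "hap_classifier_spec")
}

#' Build an initialised Bi-LSTM classifier
#' @param spec a [classifier_spec()].
#' @return an object of class `hap_classifier`.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "hap_classifier_spec"))
  set.seed(spec$seed)
  nc <- spec$n_channels
  u1 <- spec$bilstm_units[1L]
  u2 <- spec$bilstm_units[2L]
  params <- list(
    f1 = init_lstm(nc, u1), b1 = init_lstm(nc, u1),
    f2 = init_lstm(2L * u1, u2), b2 = init_lstm(2L * u1, u2),
    hidden = init_dense(2L * u2, spec$hidden_neurons),
    out = init_dense(spec$hidden_neurons, spec$n_classes)
  )
  structure(list(spec = spec, params = params, trained = FALSE,
                 history = NULL),
            class = "hap_classifier")
}

#' @export
print.hap_classifier <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat("<hap_classifier> Bi-LSTM", paste(x$spec$bilstm_units, collapse = "/"),
      "-", np, "parameters,",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

rev_time <- function(X) X[, , rev(seq_len(dim(X)[3L])), drop = FALSE]

# first bidirectional layer returns full sequences (concatenated widths);
# second returns only final states. X: (B, ch, T). Output: logits (B, K).
cl_fwd <- function(params, X, spec) {
  B <- dim(X)[1L]; T <- dim(X)[3L]
  u1 <- spec$bilstm_units[1L]; u2 <- spec$bilstm_units[2L]
  f1 <- nn_lstm_fwd(X, params$f1)
  b1 <- nn_lstm_fwd(rev_time(X), params$b1)
  H1 <- array(0, c(B, 2L * u1, T))
  H1[, seq_len(u1), ] <- f1$H
  H1[, (u1 + 1L):(2L * u1), ] <- rev_time(b1$H)
  f2 <- nn_lstm_fwd(H1, params$f2)
  b2 <- nn_lstm_fwd(rev_time(H1), params$b2)
  htot <- cbind(matrix(f2$H[, , T], B, u2), matrix(b2$H[, , T], B, u2))
  r <- nn_relu_fwd(htot)
  hid <- nn_dense_fwd(r$Y, params$hidden)
  rh <- nn_relu_fwd(hid$Y)
  out <- nn_dense_fwd(rh$Y, params$out)
  list(logits = out$Y,
       cache = list(f1 = f1, b1 = b1, f2 = f2, b2 = b2, r = r, hid = hid,
                    rh = rh, out = out, B = B, T = T, u1 = u1, u2 = u2))
}

cl_bwd <- function(params, dlogits, cache) {
  B <- cache$B; T <- cache$T; u1 <- cache$u1; u2 <- cache$u2
  out <- nn_dense_bwd(dlogits, params$out, cache$out)
  dRh <- nn_relu_bwd(out$dM, cache$rh)
  hid <- nn_dense_bwd(dRh, params$hidden, cache$hid)
  dHtot <- nn_relu_bwd(hid$dM, cache$r)
  dh_f2 <- dHtot[, seq_len(u2), drop = FALSE]
  dh_b2 <- dHtot[, (u2 + 1L):(2L * u2), drop = FALSE]
  bf2 <- nn_lstm_bwd(NULL, params$f2, cache$f2, dh_last = dh_f2)
  bb2 <- nn_lstm_bwd(NULL, params$b2, cache$b2, dh_last = dh_b2)
  dH1 <- bf2$dX + rev_time(bb2$dX)
  dF1H <- dH1[, seq_len(u1), , drop = FALSE]
  dB1H <- rev_time(dH1[, (u1 + 1L):(2L * u1), , drop = FALSE])
  bf1 <- nn_lstm_bwd(dF1H, params$f1, cache$f1)
  bb1 <- nn_lstm_bwd(dB1H, params$b1, cache$b1)
  list(
    f1 = list(W = bf1$dW, b = as.numeric(bf1$db)),
    b1 = list(W = bb1$dW, b = as.numeric(bb1$db)),
    f2 = list(W = bf2$dW, b = as.numeric(bf2$db)),
    b2 = list(W = bb2$dW, b = as.numeric(bb2$db)),
    hidden = list(W = hid$dW, b = hid$db),
    out = list(W = out$dW, b = out$db)
  )
}

#' Train the Bi-LSTM classifier
#'
#' Minimises categorical cross-entropy with Adam (reference defaults:
#' learning rate 5e-4, batch size 10, 240 passes). The classifier is always
#' trained on measured signal halves, never on forecasts.
#'
#' @param model a [build_classifier()] result.
#' @param x an `(n, input_len, channels)` array of signal windows, or a
#'   [hap_epochs()] set of matching window length.
#' @param labels character vector of class labels (ignored when `x` is a
#'   `hap_epochs` set, whose labels are used).
#' @param cfg a [train_config()]; classifier defaults are
#'   `learning_rate = 5e-4`, `batch_size = 10`.
#' @return the trained `hap_classifier` with a `history` tibble.
#' @export
fit_classifier <- function(model, x, labels = NULL,
                           cfg = train_config(learning_rate = 5e-4,
                                              batch_size = 10L)) {
  stopifnot(inherits(model, "hap_classifier"))
  if (inherits(x, "hap_epochs")) {
    labels <- x$label
    x <- x$data
  }
  n <- dim(x)[1L]
  if (is.null(n) || n == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(labels) == n)
  classes <- model$spec$classes
  y <- match(as.character(labels), classes)
  if (anyNA(y))
    stop("labels outside the configured classes: ",
         paste(setdiff(unique(labels), classes), collapse = ", "),
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  Xall <- aperm(x, c(1L, 3L, 2L))
  set.seed(cfg$seed)
  opt <- adam_init(model$params)
  history <- numeric(cfg$passes)
  for (pass in seq_len(cfg$passes)) {
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      Xb <- Xall[idx, , , drop = FALSE]
      if (!is.null(cfg$input_noise_sd) && cfg$input_noise_sd > 0)
        Xb <- Xb + array(rnorm(length(Xb), sd = cfg$input_noise_sd),
                         dim(Xb))
      fw <- cl_fwd(model$params, Xb, model$spec)
      ls <- nn_softmax_ce(fw$logits, y[idx])
      if (!is.finite(ls$loss))
        stop("non-finite training loss at pass ", pass, call. = FALSE)
      gr <- cl_bwd(model$params, ls$dlogits, fw$cache)
      st <- adam_step(model$params, gr, opt, cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
      losses <- c(losses, ls$loss)
    }
    history[pass] <- mean(losses)
    if (cfg$verbose > 0 && pass %% cfg$verbose == 0)
      message("pass ", pass, " loss ", format(history[pass], digits = 5))
  }
  model$trained <- TRUE
  model$history <- tibble::tibble(pass = seq_len(cfg$passes), loss = history)
  model$train_cfg <- cfg
  model
}

#' Classify signal windows into activities
#'
#' Returns the softmax probability distribution over the configured classes
#' and the argmax label. Inference is deterministic and independent of batch
#' composition.
#'
#' @param model a trained `hap_classifier`.
#' @param x an `input_len x channels` matrix or an
#'   `(n, input_len, channels)` array.
#' @return a tibble with one row per window: `label` plus one probability
#'   column per class.
#' @export
classify_signal <- function(model, x) {
  stopifnot(inherits(model, "hap_classifier"))
  spec <- model$spec
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) != 3L || dim(x)[2L] != spec$input_len ||
      dim(x)[3L] != spec$n_channels)
    stop("input must be (", spec$input_len, " x ", spec$n_channels, ")",
         call. = FALSE)
  fw <- cl_fwd(model$params, aperm(x, c(1L, 3L, 2L)), spec)
  P <- softmax_rows(fw$logits)
  colnames(P) <- spec$classes
  tibble::tibble(label = spec$classes[max.col(P, ties.method = "first")]) |>
    dplyr::bind_cols(tibble::as_tibble(P))
}

#' @export
predict.hap_classifier <- function(object, newdata, ...) {
  classify_signal(object, newdata)
}

#' @export
tidy.hap_classifier <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble(pass = integer(0),
                                                loss = numeric(0)))
  x$history
}

#' @export
glance.hap_classifier <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(rapply(x$params, length, how = "unlist")),
    bilstm_units = paste(x$spec$bilstm_units, collapse = "/"),
    n_classes = x$spec$n_classes,
    trained = x$trained,
    passes = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}
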
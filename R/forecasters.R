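# The three forecasting architectures. All map an observed (input_len x 6)
# signal half to the future (output_len x 6) half:
#   conv2lstm          two 1-D conv blocks -> two LSTMs -> dropout -> linear
#   seq2seq_lstm       encoder LSTM -> context vector + start token ->
#                      decoder LSTM (teacher forced in training,
#                      autoregressive at inference) -> linear
#   seq2seq_lstm_pe_ma conv embedding + positional encoding -> 2-layer LSTM
#                      encoder (full sequences) -> 2-layer LSTM decoder ->
#                      multi-head self-attention added residually -> linear

#' Forecaster architecture specification
#'
#' Defaults follow the reference architectures: Conv2LSTM uses two conv
#' layers of 32 filters with kernel size 6 and two 256-unit LSTMs with 0.5
#' dropout; Seq2Seq-LSTM uses 100-unit encoder/decoder LSTMs; the PE-MA
#' variant embeds into `d_model` (default 96) channels, uses `d_model`-unit
#' LSTMs so the residual attention add is width-consistent, and 16 attention
#' heads. Reduced sizes (e.g. `units = 32`, `d_model = 32`, `n_heads = 4`)
#' train in minutes on one CPU.
#'
#' @param architecture one of `"conv2lstm"`, `"seq2seq_lstm"`,
#'   `"seq2seq_lstm_pe_ma"`.
#' @param input_len observed samples per epoch half (default 256).
#' @param output_len forecasted samples (default 256); must equal
#'   `input_len` for the direct sequence-mapping architectures
#'   (`conv2lstm`, `seq2seq_lstm_pe_ma`).
#' @param n_channels signal channels (default 6).
#' @param units LSTM width; architecture-specific default (256 conv2lstm,
#'   100 seq2seq_lstm, `d_model` for the PE-MA variant).
#' @param filters,kernel_size conv block shape for `conv2lstm`.
#' @param dropout dropout rate before the conv2lstm head (default 0.5).
#' @param d_model embedding width for the PE-MA variant (default 96);
#'   must be divisible by `n_heads`.
#' @param n_heads attention heads (default 16).
#' @param embed_kernel kernel size of the 1-D conv resize before the
#'   positional encoding (default 1, a per-sample linear embedding).
#' @param pe_base positional-encoding wavelength base (default 10000).
#' @param seed seed for parameter initialisation.
#' @return an object of class `hap_forecaster_spec`.
#' @export
forecaster_spec <- function(architecture = c("seq2seq_lstm_pe_ma",
                                             "seq2seq_lstm", "conv2lstm"),
                            input_len = 256L, output_len = 256L,
                            n_channels = 6L, units = NULL,
                            filters = 32L, kernel_size = 6L, dropout = 0.5,
                            d_model = 96L, n_heads = 16L, embed_kernel = 1L,
                            pe_base = 10000, seed = 1L) {
  architecture <- match.arg(architecture)
  if (architecture != "seq2seq_lstm" && input_len != output_len)
    stop("`", architecture, "` maps the sequence directly; ",
         "`input_len` must equal `output_len`", call. = FALSE)
  if (architecture == "seq2seq_lstm_pe_ma") {
    if (d_model %% n_heads != 0L)
      stop("`d_model` must be divisible by `n_heads`", call. = FALSE)
    if (is.null(units)) units <- d_model
    if (units != d_model)
      stop("the PE-MA variant uses `units = d_model` so the residual ",
           "attention add is width-consistent", call. = FALSE)
  }
  if (is.null(units))
    units <- switch(architecture, conv2lstm = 256L, seq2seq_lstm = 100L)
  structure(list(architecture = architecture,
                 input_len = as.integer(input_len),
                 output_len = as.integer(output_len),
                 n_channels = as.integer(n_channels),
                 units = as.integer(units), filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size), dropout = dropout,
                 d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 embed_kernel = as.integer(embed_kernel), pe_base = pe_base,
                 seed = as.integer(seed)),
            class = "hap_forecaster_spec")
}

#' Build an initialised forecaster
#'
#' Parameter initialisation is fully determined by `spec$seed`: two builds
#' from the same spec are identical.
#'
#' @param spec a [forecaster_spec()].
#' @return an object of class `hap_forecaster`.
#' @export
build_forecaster <- function(spec) {
  stopifnot(inherits(spec, "hap_forecaster_spec"))
  set.seed(spec$seed)
  nc <- spec$n_channels
  u <- spec$units
  params <- switch(spec$architecture,
    conv2lstm = list(
      conv1 = init_conv1d(spec$kernel_size, nc, spec$filters),
      conv2 = init_conv1d(spec$kernel_size, spec$filters, spec$filters),
      lstm1 = init_lstm(spec$filters, u),
      lstm2 = init_lstm(u, u),
      head = init_dense(u, nc)
    ),
    seq2seq_lstm = list(
      enc = init_lstm(nc, u),
      dec = init_lstm(nc + u, u),
      head = init_dense(u, nc)
    ),
    seq2seq_lstm_pe_ma = list(
      embed = init_conv1d(spec$embed_kernel, nc, spec$d_model),
      enc1 = init_lstm(spec$d_model, u),
      enc2 = init_lstm(u, u),
      dec1 = init_lstm(u, u),
      dec2 = init_lstm(u, u),
      mha = init_mha(spec$d_model),
      head = init_dense(spec$d_model, nc)
    )
  )
  pe <- if (spec$architecture == "seq2seq_lstm_pe_ma") {
    positional_encoding(spec$input_len, spec$d_model, spec$pe_base)
  }
  structure(list(spec = spec, params = params, pe = pe,
                 trained = FALSE, history = NULL),
            class = "hap_forecaster")
}

#' @export
print.hap_forecaster <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat("<hap_forecaster>", x$spec$architecture, "-", np, "parameters,",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

# ---- forward/backward passes ------------------------------------------------
# X, Y are (B, channels, T) tensors.

fc_fwd_conv2lstm <- function(params, X, spec, train) {
  k <- spec$kernel_size
  c1 <- nn_conv1d_fwd(X, params$conv1, k)
  r1 <- nn_relu_fwd(c1$Y)
  c2 <- nn_conv1d_fwd(r1$Y, params$conv2, k)
  r2 <- nn_relu_fwd(c2$Y)
  l1 <- nn_lstm_fwd(r2$Y, params$lstm1)
  l2 <- nn_lstm_fwd(l1$H, params$lstm2)
  dr <- nn_dropout_fwd(l2$H, spec$dropout, train)
  B <- dim(X)[1L]; T <- dim(X)[3L]
  hd <- nn_dense_fwd(bt_flat(dr$Y), params$head)
  list(Yhat = bt_unflat(hd$Y, B, T),
       cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, l1 = l1, l2 = l2,
                    dr = dr, hd = hd, B = B, T = T))
}

fc_bwd_conv2lstm <- function(params, dYhat, cache, spec) {
  k <- spec$kernel_size
  hd <- nn_dense_bwd(bt_flat(dYhat), params$head, cache$hd)
  dDr <- bt_unflat(hd$dM, cache$B, cache$T)
  dL2H <- nn_dropout_bwd(dDr, cache$dr)
  b2 <- nn_lstm_bwd(dL2H, params$lstm2, cache$l2)
  b1 <- nn_lstm_bwd(b2$dX, params$lstm1, cache$l1)
  dR2 <- nn_relu_bwd(b1$dX, cache$r2)
  bc2 <- nn_conv1d_bwd(dR2, params$conv2, cache$c2, k)
  dR1 <- nn_relu_bwd(bc2$dX, cache$r1)
  bc1 <- nn_conv1d_bwd(dR1, params$conv1, cache$c1, k)
  list(
    conv1 = list(W = bc1$dW, b = bc1$db),
    conv2 = list(W = bc2$dW, b = bc2$db),
    lstm1 = list(W = b1$dW, b = as.numeric(b1$db)),
    lstm2 = list(W = b2$dW, b = as.numeric(b2$db)),
    head = list(W = hd$dW, b = hd$db)
  )
}

# teacher-forced training pass; Yprev supplies the decoder inputs
fc_fwd_seq2seq <- function(params, X, spec, Yprev) {
  B <- dim(X)[1L]; nc <- dim(X)[2L]; Tin <- dim(X)[3L]
  Tout <- spec$output_len
  u <- spec$units
  enc <- nn_lstm_fwd(X, params$enc)
  hT <- matrix(enc$H[, , Tin], B, u)
  cT <- matrix(enc$C[, , Tin], B, u)
  D <- array(0, c(B, nc + u, Tout))
  D[, seq_len(nc), ] <- Yprev
  D[, (nc + 1L):(nc + u), ] <- hT # context Z tiled across steps
  dec <- nn_lstm_fwd(D, params$dec, h0 = hT, c0 = cT)
  hd <- nn_dense_fwd(bt_flat(dec$H), params$head)
  list(Yhat = bt_unflat(hd$Y, B, Tout),
       cache = list(enc = enc, dec = dec, hd = hd, B = B, nc = nc,
                    Tin = Tin, Tout = Tout, u = u))
}

fc_bwd_seq2seq <- function(params, dYhat, cache) {
  hd <- nn_dense_bwd(bt_flat(dYhat), params$head, cache$hd)
  dDecH <- bt_unflat(hd$dM, cache$B, cache$Tout)
  bd <- nn_lstm_bwd(dDecH, params$dec, cache$dec)
  # gradient into the tiled context: sum over decoder steps, plus the
  # gradient through the decoder's initial state
  nc <- cache$nc; u <- cache$u
  dZ <- apply(bd$dX[, (nc + 1L):(nc + u), , drop = FALSE], c(1L, 2L), sum)
  be <- nn_lstm_bwd(NULL, params$enc, cache$enc,
                    dh_last = bd$dh0 + dZ, dc_last = bd$dc0)
  list(
    enc = list(W = be$dW, b = as.numeric(be$db)),
    dec = list(W = bd$dW, b = as.numeric(bd$db)),
    head = list(W = hd$dW, b = hd$db)
  )
}

fc_fwd_pema <- function(params, X, spec, pe) {
  B <- dim(X)[1L]; T <- dim(X)[3L]
  u <- spec$units
  em <- nn_conv1d_fwd(X, params$embed, spec$embed_kernel)
  pet <- array(rep(as.vector(t(pe)), each = B), dim(em$Y))
  E0 <- em$Y + pet
  e1 <- nn_lstm_fwd(E0, params$enc1)
  e2 <- nn_lstm_fwd(e1$H, params$enc2)
  # decoder layers start from the matching encoder layer's final state,
  # avoiding a cold-start transient at the beginning of the forecast
  d1 <- nn_lstm_fwd(e2$H, params$dec1,
                    h0 = matrix(e1$H[, , T], B, u),
                    c0 = matrix(e1$C[, , T], B, u))
  d2 <- nn_lstm_fwd(d1$H, params$dec2,
                    h0 = matrix(e2$H[, , T], B, u),
                    c0 = matrix(e2$C[, , T], B, u))
  at <- nn_mha_fwd(d2$H, params$mha, spec$n_heads)
  R <- d2$H + at$Y
  hd <- nn_dense_fwd(bt_flat(R), params$head)
  list(Yhat = bt_unflat(hd$Y, B, T),
       cache = list(em = em, e1 = e1, e2 = e2, d1 = d1, d2 = d2, at = at,
                    hd = hd, B = B, T = T))
}

fc_bwd_pema <- function(params, dYhat, cache, spec) {
  hd <- nn_dense_bwd(bt_flat(dYhat), params$head, cache$hd)
  dR <- bt_unflat(hd$dM, cache$B, cache$T)
  ba <- nn_mha_bwd(dR, params$mha, cache$at)
  dD2 <- dR + ba$dX # residual: gradient flows both ways
  b2 <- nn_lstm_bwd(dD2, params$dec2, cache$d2)
  b1 <- nn_lstm_bwd(b2$dX, params$dec1, cache$d1)
  # decoder initial states came from the encoder layers' final states, so
  # those gradients flow back into the encoders alongside the sequence path
  be2 <- nn_lstm_bwd(b1$dX, params$enc2, cache$e2,
                     dh_last = b2$dh0, dc_last = b2$dc0)
  be1 <- nn_lstm_bwd(be2$dX, params$enc1, cache$e1,
                     dh_last = b1$dh0, dc_last = b1$dc0)
  # positional-encoding add is constant: gradient passes through unchanged
  bem <- nn_conv1d_bwd(be1$dX, params$embed, cache$em, spec$embed_kernel)
  list(
    embed = list(W = bem$dW, b = bem$db),
    enc1 = list(W = be1$dW, b = as.numeric(be1$db)),
    enc2 = list(W = be2$dW, b = as.numeric(be2$db)),
    dec1 = list(W = b1$dW, b = as.numeric(b1$db)),
    dec2 = list(W = b2$dW, b = as.numeric(b2$db)),
    mha = ba$grads,
    head = list(W = hd$dW, b = hd$db)
  )
}

# one training forward+backward on a batch; returns loss and grads
fc_train_batch <- function(model, X, Y, teacher_forcing) {
  spec <- model$spec
  p <- model$params
  if (spec$architecture == "conv2lstm") {
    fw <- fc_fwd_conv2lstm(p, X, spec, train = TRUE)
    ls <- nn_mse(fw$Yhat, Y)
    gr <- fc_bwd_conv2lstm(p, ls$dYhat, fw$cache, spec)
  } else if (spec$architecture == "seq2seq_lstm") {
    nc <- spec$n_channels
    B <- dim(X)[1L]
    Tin <- spec$input_len; Tout <- spec$output_len
    start <- matrix(X[, , Tin], B, nc)
    if (isFALSE(teacher_forcing)) {
      # train through the autoregressive rollout itself, with gradients
      # flowing through the prediction feedback loop
      u <- spec$units
      enc <- nn_lstm_fwd(X, p$enc)
      hT <- matrix(enc$H[, , Tin], B, u)
      cT <- matrix(enc$C[, , Tin], B, u)
      ar <- lstm_ar_forward_cpp(start, hT, p$dec$W, p$dec$b, hT, cT,
                                p$head$W, p$head$b, Tout)
      ls <- nn_mse(ar$Y, Y)
      bk <- lstm_ar_backward_cpp(ls$dYhat, ar$Yin, hT, p$dec$W, p$head$W,
                                 ar$H, ar$C, ar$G, hT, cT)
      # the encoder's final state serves as both context Z and the
      # decoder's initial state
      be <- nn_lstm_bwd(NULL, p$enc, enc,
                        dh_last = bk$dZ + bk$dh0, dc_last = bk$dc0)
      return(list(loss = ls$loss, grads = list(
        enc = list(W = be$dW, b = as.numeric(be$db)),
        dec = list(W = bk$dW, b = as.numeric(bk$db)),
        head = list(W = bk$dWout, b = as.numeric(bk$dbout))
      )))
    }
    Yteacher <- array(0, c(B, nc, Tout))
    Yteacher[, , 1L] <- start
    if (Tout > 1L) Yteacher[, , 2:Tout] <- Y[, , 1:(Tout - 1L)]
    if (teacher_forcing >= 1) {
      Yprev <- Yteacher
    } else {
      # scheduled sampling: each step uses the teacher value with
      # probability p, otherwise the model's own (detached) prediction
      u <- spec$units
      enc <- nn_lstm_fwd(X, p$enc)
      hT <- matrix(enc$H[, , Tin], B, u)
      cT <- matrix(enc$C[, , Tin], B, u)
      usetf <- matrix(as.numeric(runif(B * Tout) < teacher_forcing), B, Tout)
      usetf[, 1L] <- 1
      Yprev <- lstm_scheduled_rollout_cpp(Yteacher, usetf, hT,
                                          p$dec$W, p$dec$b, hT, cT,
                                          p$head$W, p$head$b)
    }
    fw <- fc_fwd_seq2seq(p, X, spec, Yprev)
    ls <- nn_mse(fw$Yhat, Y)
    gr <- fc_bwd_seq2seq(p, ls$dYhat, fw$cache)
  } else {
    fw <- fc_fwd_pema(p, X, spec, model$pe)
    ls <- nn_mse(fw$Yhat, Y)
    gr <- fc_bwd_pema(p, ls$dYhat, fw$cache, spec)
  }
  list(loss = ls$loss, grads = gr)
}

fc_decode_seq2seq <- function(params, X, spec) {
  B <- dim(X)[1L]; nc <- spec$n_channels; Tin <- dim(X)[3L]
  u <- spec$units
  enc <- nn_lstm_fwd(X, params$enc)
  hT <- matrix(enc$H[, , Tin], B, u)
  cT <- matrix(enc$C[, , Tin], B, u)
  start <- matrix(X[, , Tin], B, nc)
  lstm_decode_cpp(start, hT, params$dec$W, params$dec$b, hT, cT,
                  params$head$W, params$head$b, spec$output_len)
}

# inference pass: (B, ch, T_in) -> (B, ch, T_out); dropout disabled,
# seq2seq decodes autoregressively from the start token
fc_infer <- function(model, X) {
  spec <- model$spec
  switch(spec$architecture,
    conv2lstm = fc_fwd_conv2lstm(model$params, X, spec, train = FALSE)$Yhat,
    seq2seq_lstm = fc_decode_seq2seq(model$params, X, spec),
    seq2seq_lstm_pe_ma = fc_fwd_pema(model$params, X, spec, model$pe)$Yhat
  )
}

# ---- training ---------------------------------------------------------------

#' Training configuration for forecasters and the classifier
#'
#' Reference defaults: forecasters train for 240 passes with batch size 25,
#' Adam, learning rate 3e-4, mean-squared-error loss; the classifier uses
#' batch size 10 and learning rate 5e-4 with categorical cross-entropy.
#'
#' @param passes full passes over the training set (default 240).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param teacher_forcing decoder conditioning for seq2seq training:
#'   `TRUE` (always condition on the true previous sample), `FALSE`
#'   (always on the model's own detached prediction), a probability in
#'   `[0, 1]`, or `"scheduled"` (linear decay of the probability from 1 to
#'   0 over the run -- scheduled sampling, so training matches the
#'   autoregressive feedback used at inference). Ignored by the direct
#'   sequence-mapping architectures.
#' @param input_noise_sd standard deviation of Gaussian jitter added to
#'   each training batch's inputs (0 disables). A small jitter regularises
#'   the classifier against signal perturbations such as forecast error.
#' @param seed seed governing batch shuffling, dropout and jitter.
#' @param verbose print loss every `verbose` passes (0 = silent).
#' @return a list of class `hap_train_config`.
#' @export
train_config <- function(passes = 240L, batch_size = 25L,
                         learning_rate = 3e-4, teacher_forcing = TRUE,
                         input_noise_sd = 0, seed = 1L, verbose = 0L) {
  ok <- isTRUE(teacher_forcing) || isFALSE(teacher_forcing) ||
    identical(teacher_forcing, "scheduled") ||
    (is.numeric(teacher_forcing) && teacher_forcing >= 0 &&
       teacher_forcing <= 1)
  if (!ok)
    stop("`teacher_forcing` must be TRUE, FALSE, a probability or ",
         "\"scheduled\"", call. = FALSE)
  structure(list(passes = as.integer(passes),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 teacher_forcing = teacher_forcing,
                 input_noise_sd = input_noise_sd,
                 seed = as.integer(seed), verbose = as.integer(verbose)),
            class = "hap_train_config")
}

# per-pass teacher-forcing probability
tf_prob <- function(teacher_forcing, pass, passes) {
  if (isTRUE(teacher_forcing)) return(1)
  if (isFALSE(teacher_forcing)) return(0)
  if (identical(teacher_forcing, "scheduled"))
    return(1 - (pass - 1) / max(1L, passes - 1L))
  teacher_forcing
}

#' Train a forecaster on epoch pairs
#'
#' Minimises the mean squared error between the forecasted and measured
#' future halves with Adam. The run is fully reproducible from the
#' configuration seed.
#'
#' @param model a [build_forecaster()] result.
#' @param pairs a [make_pairs()] object (or a list with `observed` and
#'   `future` arrays of shape `(n, len, channels)`).
#' @param cfg a [train_config()].
#' @return the trained `hap_forecaster`, with a `history` tibble
#'   (`pass`, `loss`).
#' @export
fit_forecaster <- function(model, pairs,
                           cfg = train_config(learning_rate = 3e-4,
                                              batch_size = 25L)) {
  stopifnot(inherits(model, "hap_forecaster"))
  n <- dim(pairs$observed)[1L]
  if (is.null(n) || n == 0) stop("empty training set", call. = FALSE)
  # to (B, ch, T) layout
  Xall <- aperm(pairs$observed, c(1L, 3L, 2L))
  Yall <- aperm(pairs$future, c(1L, 3L, 2L))
  if (dim(Xall)[3L] != model$spec$input_len)
    stop("observed length ", dim(Xall)[3L], " does not match spec input_len ",
         model$spec$input_len, call. = FALSE)
  set.seed(cfg$seed)
  opt <- adam_init(model$params)
  history <- numeric(cfg$passes)
  for (pass in seq_len(cfg$passes)) {
    ord <- sample.int(n)
    losses <- c()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
      res <- fc_train_batch(model,
                            Xall[idx, , , drop = FALSE],
                            Yall[idx, , , drop = FALSE],
                            if (isFALSE(cfg$teacher_forcing)) FALSE
                            else tf_prob(cfg$teacher_forcing, pass,
                                         cfg$passes))
      if (!is.finite(res$loss))
        stop("non-finite training loss at pass ", pass,
             "; lower the learning rate", call. = FALSE)
      st <- adam_step(model$params, res$grads, opt, cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
      losses <- c(losses, res$loss)
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

#' Forecast the future signal half from the observed half
#'
#' Inference is deterministic (dropout disabled) and never mutates the
#' model. The seq2seq architecture decodes autoregressively: the start token
#' is the last observed sample and each predicted step is fed back as the
#' next decoder input.
#'
#' @param model a (typically trained) `hap_forecaster`.
#' @param observed an `input_len x channels` matrix, or an
#'   `(n, input_len, channels)` array for batched inference.
#' @return an `output_len x channels` matrix (or `(n, output_len, channels)`
#'   array), finite everywhere.
#' @export
forecast_signal <- function(model, observed) {
  stopifnot(inherits(model, "hap_forecaster"))
  spec <- model$spec
  single <- is.matrix(observed)
  X <- if (single) {
    array(observed, c(1L, dim(observed)))
  } else observed
  if (length(dim(X)) != 3L || dim(X)[2L] != spec$input_len ||
      dim(X)[3L] != spec$n_channels)
    stop("`observed` must be (", spec$input_len, " x ", spec$n_channels,
         "), got ", paste(dim(observed), collapse = " x "), call. = FALSE)
  Yhat <- fc_infer(model, aperm(X, c(1L, 3L, 2L)))
  out <- aperm(Yhat, c(1L, 3L, 2L))
  if (single) {
    m <- out[1L, , ]
    dim(m) <- dim(out)[2:3]
    m
  } else out
}

#' @export
predict.hap_forecaster <- function(object, newdata, ...) {
  forecast_signal(object, newdata)
}

#' @export
tidy.hap_forecaster <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble(pass = integer(0),
                                                loss = numeric(0)))
  x$history
}

#' @export
glance.hap_forecaster <- function(x, ...) {
  tibble::tibble(
    architecture = x$spec$architecture,
    n_parameters = sum(rapply(x$params, length, how = "unlist")),
    units = x$spec$units,
    trained = x$trained,
    passes = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}
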
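# Minimal neural-network engine backing the forecasters and the classifier.
# Batch tensors are 3-D arrays laid out (batch, feature, time) to match the
# compiled LSTM kernels; time-distributed layers operate on the flattened
# (batch*time, feature) matrix. Everything here is internal.

# ---- tensor helpers ---------------------------------------------------------

# (B, d, T) array -> (B*T, d) matrix; row index = b + B*(t-1)
bt_flat <- function(X) {
  dm <- dim(X)
  M <- aperm(X, c(1L, 3L, 2L))
  dim(M) <- c(dm[1L] * dm[3L], dm[2L])
  M
}

bt_unflat <- function(M, B, T) {
  A <- M
  dim(A) <- c(B, T, ncol(M))
  aperm(A, c(1L, 3L, 2L))
}

# stack a list of (T x d) matrices (one per sample) into a (B, d, T) tensor
stack_bdt <- function(mats) {
  B <- length(mats)
  T <- nrow(mats[[1L]])
  d <- ncol(mats[[1L]])
  X <- array(0, c(B, d, T))
  for (b in seq_len(B)) X[b, , ] <- t(mats[[b]])
  X
}

# ---- initialisation ---------------------------------------------------------

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_dense <- function(nin, nout) {
  list(W = glorot(nin, nout), b = numeric(nout))
}

# forget-gate bias starts at 1 (standard stabiliser for gradient flow)
init_lstm <- function(nin, units) {
  b <- numeric(4L * units)
  b[(units + 1L):(2L * units)] <- 1
  list(W = glorot(nin + units, 4L * units) * 0.5, b = b)
}

init_conv1d <- function(k, nin, nout) {
  list(W = glorot(k * nin, nout), b = numeric(nout))
}

init_mha <- function(d_model) {
  list(
    Wq = glorot(d_model, d_model), bq = numeric(d_model),
    Wk = glorot(d_model, d_model), bk = numeric(d_model),
    Wv = glorot(d_model, d_model), bv = numeric(d_model),
    Wo = glorot(d_model, d_model), bo = numeric(d_model)
  )
}

# ---- dense (time-distributed when fed a flattened tensor) -------------------

nn_dense_fwd <- function(M, p) {
  Y <- M %*% p$W
  Y <- Y + rep(p$b, each = nrow(M))
  list(Y = Y, M = M)
}

nn_dense_bwd <- function(dY, p, cache) {
  list(
    dM = dY %*% t(p$W),
    dW = crossprod(cache$M, dY),
    db = colSums(dY)
  )
}

# ---- 1-D convolution, 'same' padding ---------------------------------------

conv1d_pad <- function(k) {
  left <- (k - 1L) %/% 2L
  c(left = left, right = k - 1L - left)
}

# X: (B, d, T); weights viewed as im2col matrix (k*d, f)
nn_conv1d_fwd <- function(X, p, k) {
  B <- dim(X)[1L]; d <- dim(X)[2L]; T <- dim(X)[3L]
  pad <- conv1d_pad(k)
  Xp <- array(0, c(B, d, T + k - 1L))
  Xp[, , (pad[["left"]] + 1L):(pad[["left"]] + T)] <- X
  Xcol <- matrix(0, B * T, k * d)
  for (j in seq_len(k)) {
    Xcol[, ((j - 1L) * d + 1L):(j * d)] <- bt_flat(Xp[, , j:(j + T - 1L), drop = FALSE])
  }
  Y <- Xcol %*% p$W
  Y <- Y + rep(p$b, each = nrow(Y))
  list(Y = bt_unflat(Y, B, T), Xcol = Xcol, dims = c(B, d, T))
}

nn_conv1d_bwd <- function(dY, p, cache, k) {
  B <- cache$dims[1L]; d <- cache$dims[2L]; T <- cache$dims[3L]
  pad <- conv1d_pad(k)
  dYf <- bt_flat(dY)
  dW <- crossprod(cache$Xcol, dYf)
  db <- colSums(dYf)
  dXcol <- dYf %*% t(p$W)
  dXp <- array(0, c(B, d, T + k - 1L))
  for (j in seq_len(k)) {
    dXp[, , j:(j + T - 1L)] <- dXp[, , j:(j + T - 1L), drop = FALSE] +
      bt_unflat(dXcol[, ((j - 1L) * d + 1L):(j * d), drop = FALSE], B, T)
  }
  dX <- dXp[, , (pad[["left"]] + 1L):(pad[["left"]] + T), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- elementwise ------------------------------------------------------------

nn_relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

nn_relu_bwd <- function(dY, cache) dY * cache$mask

nn_dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- array(runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

nn_dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- LSTM wrappers over the compiled kernels --------------------------------

nn_lstm_fwd <- function(X, p, h0 = NULL, c0 = NULL) {
  B <- dim(X)[1L]
  units <- ncol(p$W) / 4L
  if (is.null(h0)) h0 <- matrix(0, B, units)
  if (is.null(c0)) c0 <- matrix(0, B, units)
  out <- lstm_forward_cpp(X, p$W, p$b, h0, c0)
  out$X <- X
  out$h0 <- h0
  out$c0 <- c0
  out
}

nn_lstm_bwd <- function(dH, p, cache, dh_last = NULL, dc_last = NULL) {
  B <- dim(cache$X)[1L]
  units <- ncol(p$W) / 4L
  if (is.null(dh_last)) dh_last <- matrix(0, B, units)
  if (is.null(dc_last)) dc_last <- matrix(0, B, units)
  if (is.null(dH)) dH <- array(0, dim(cache$H))
  lstm_backward_cpp(dH, dh_last, dc_last, cache$X, p$W,
                    cache$H, cache$C, cache$G, cache$h0, cache$c0)
}

lstm_final_h <- function(cache) {
  T <- dim(cache$H)[3L]
  cache$H[, , T, drop = TRUE]
}

# ---- losses -----------------------------------------------------------------

nn_mse <- function(Yhat, Y) {
  D <- Yhat - Y
  list(loss = mean(D^2), dYhat = 2 * D / length(D))
}

# logits: (B, K); y: integer class index in 1..K
nn_softmax_ce <- function(logits, y) {
  B <- nrow(logits)
  Z <- logits - apply(logits, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / B, probs = P)
}

softmax_rows <- function(S) {
  rmax <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - rmax)
  E / rowSums(E)
}

# ---- Adam -------------------------------------------------------------------
# Parameters are nested named lists of numeric arrays (one sublist per layer);
# the optimiser walks the structure recursively.

params_zero <- function(params) {
  rapply(params, function(p) p * 0, classes = "ANY", how = "replace")
}

adam_init <- function(params) {
  list(m = params_zero(params), v = params_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  state$m <- res$m
  state$v <- res$v
  list(params = res$p, state = state)
}

# elementwise sum of two grad structures with identical shape
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
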
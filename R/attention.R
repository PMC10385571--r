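#' Sinusoidal positional encoding
#'
#' Builds the deterministic sine/cosine position matrix added to embedded
#' inputs so a recurrent or attention layer can exploit absolute sample
#' position. Entry `(pos, 2i)` is `sin(pos / base^(2i/d_model))` and entry
#' `(pos, 2i+1)` is `cos` of the same argument, with `pos` counted from 0;
#' the wavelengths form a geometric progression from `2*pi` to `base*2*pi`.
#'
#' @param max_len number of positions (rows); row `r` encodes position `r - 1`.
#' @param d_model embedding width (columns); must be even.
#' @param base wavelength base of the geometric progression (default 10000).
#' @return a `max_len` x `d_model` numeric matrix with entries in `[-1, 1]`.
#' @examples
#' pe <- positional_encoding(4, 8)
#' pe[1, ] # position 0: sines are 0, cosines are 1
#' @export
positional_encoding <- function(max_len, d_model, base = 10000) {
  if (d_model %% 2L != 0L) stop("`d_model` must be even", call. = FALSE)
  if (max_len < 1L) stop("`max_len` must be >= 1", call. = FALSE)
  pos <- seq_len(max_len) - 1
  i <- seq_len(d_model %/% 2L) - 1
  ang <- outer(pos, base^(-2 * i / d_model)) # max_len x d_model/2
  PE <- matrix(0, max_len, d_model)
  PE[, 2 * i + 1] <- sin(ang)
  PE[, 2 * i + 2] <- cos(ang)
  PE
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`. The softmax weight matrix is
#' row-stochastic: every query distributes a unit of attention over the keys.
#'
#' @param Q queries, `n_q x d_k` matrix.
#' @param K keys, `n_k x d_k` matrix.
#' @param V values, `n_k x d_v` matrix.
#' @param return_weights if `TRUE`, attach the attention weight matrix as the
#'   `"weights"` attribute of the result.
#' @return `n_q x d_v` matrix of attended values.
#' @examples
#' scaled_dot_attention(matrix(1, 1, 2), matrix(1, 1, 2), matrix(5, 1, 1))
#' @export
scaled_dot_attention <- function(Q, K, V, return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop("`Q` and `K` must have the same key dimension", call. = FALSE)
  if (nrow(K) != nrow(V))
    stop("`K` and `V` must have the same number of rows", call. = FALSE)
  W <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  out <- W %*% V
  if (return_weights) attr(out, "weights") <- W
  out
}

#' Multi-head attention specification
#'
#' Creates the projection weights for [multi_head_attention()]. With
#' `weights = "identity"` and one head the layer reduces exactly to
#' [scaled_dot_attention()] of the input with itself, which is useful for
#' testing.
#'
#' @param d_model input/output width; must be divisible by `n_heads`.
#' @param n_heads number of parallel attention heads (default 16).
#' @param seed optional seed for the random projection initialisation.
#' @param weights `"glorot"` (random) or `"identity"` projections.
#' @return an object of class `attention_spec`.
#' @export
attention_spec <- function(d_model, n_heads = 16L, seed = NULL,
                           weights = c("glorot", "identity")) {
  weights <- match.arg(weights)
  n_heads <- as.integer(n_heads)
  if (d_model %% n_heads != 0L)
    stop("`d_model` (", d_model, ") must be divisible by `n_heads` (",
         n_heads, ")", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  params <- if (weights == "identity") {
    eye <- diag(d_model)
    list(Wq = eye, bq = numeric(d_model), Wk = eye, bk = numeric(d_model),
         Wv = eye, bv = numeric(d_model), Wo = eye, bo = numeric(d_model))
  } else {
    init_mha(d_model)
  }
  structure(list(d_model = as.integer(d_model), n_heads = n_heads,
                 d_k = as.integer(d_model %/% n_heads), params = params),
            class = "attention_spec")
}

#' Multi-head self-attention over a sequence
#'
#' Projects the input into per-head queries, keys and values, runs scaled
#' dot-product attention in each head, concatenates the heads and applies the
#' output projection. Output shape equals input shape.
#'
#' @param x a `seq_len x d_model` matrix (one sequence).
#' @param spec an [attention_spec()].
#' @return a matrix of the same shape as `x`.
#' @export
multi_head_attention <- function(x, spec) {
  stopifnot(inherits(spec, "attention_spec"))
  x <- as.matrix(x)
  if (ncol(x) != spec$d_model)
    stop("input width ", ncol(x), " does not match spec d_model ",
         spec$d_model, call. = FALSE)
  X <- array(t(x), c(1L, ncol(x), nrow(x)))
  fw <- nn_mha_fwd(X, spec$params, spec$n_heads)
  t(fw$Y[1L, , ])
}

# ---- internal batched self-attention (forward + backward) -------------------

# X: (B, D, T). Projections are single large matrix products on the
# flattened tensor; the per-sample, per-head attention loop runs in the
# compiled kernel. Returns Y: (B, D, T) plus caches for the backward pass.
nn_mha_fwd <- function(X, p, n_heads) {
  B <- dim(X)[1L]; D <- dim(X)[2L]; T <- dim(X)[3L]
  Xf <- bt_flat(X)
  Qf <- Xf %*% p$Wq + rep(p$bq, each = nrow(Xf))
  Kf <- Xf %*% p$Wk + rep(p$bk, each = nrow(Xf))
  Vf <- Xf %*% p$Wv + rep(p$bv, each = nrow(Xf))
  to_tdb <- function(M) aperm(bt_unflat(M, B, T), c(3L, 2L, 1L))
  Qc <- to_tdb(Qf); Kc <- to_tdb(Kf); Vc <- to_tdb(Vf)
  at <- mha_attend_cpp(Qc, Kc, Vc, n_heads)
  Of <- bt_flat(aperm(at$O, c(3L, 2L, 1L)))
  Yf <- Of %*% p$Wo + rep(p$bo, each = nrow(Of))
  list(Y = bt_unflat(Yf, B, T),
       Xf = Xf, Qc = Qc, Kc = Kc, Vc = Vc, A = at$A, Of = Of,
       dims = c(B, D, T), n_heads = n_heads)
}

nn_mha_bwd <- function(dY, p, cache) {
  B <- cache$dims[1L]; T <- cache$dims[3L]
  dYf <- bt_flat(dY)
  dWo <- crossprod(cache$Of, dYf)
  dbo <- colSums(dYf)
  dOf <- dYf %*% t(p$Wo)
  dOc <- aperm(bt_unflat(dOf, B, T), c(3L, 2L, 1L))
  bk <- mha_attend_bwd_cpp(dOc, cache$Qc, cache$Kc, cache$Vc, cache$A,
                           cache$n_heads)
  from_tdb <- function(A) bt_flat(aperm(A, c(3L, 2L, 1L)))
  dQf <- from_tdb(bk$dQ); dKf <- from_tdb(bk$dK); dVf <- from_tdb(bk$dV)
  dXf <- dQf %*% t(p$Wq) + dKf %*% t(p$Wk) + dVf %*% t(p$Wv)
  grads <- list(
    Wq = crossprod(cache$Xf, dQf), bq = colSums(dQf),
    Wk = crossprod(cache$Xf, dKf), bk = colSums(dKf),
    Wv = crossprod(cache$Xf, dVf), bv = colSums(dVf),
    Wo = dWo, bo = dbo
  )
  list(dX = bt_unflat(dXf, B, T), grads = grads)
}
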
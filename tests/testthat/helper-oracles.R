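# Independent brute-force oracles used across tests. These deliberately use
# plain loops and base arithmetic, not the package's implementations.

oracle_rmse <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  sqrt(s / length(y))
}

oracle_corr <- function(y, yhat) {
  my <- sum(y) / length(y)
  mh <- sum(yhat) / length(yhat)
  num <- 0; dy <- 0; dh <- 0
  for (i in seq_along(y)) {
    num <- num + (y[i] - my) * (yhat[i] - mh)
    dy <- dy + (y[i] - my)^2
    dh <- dh + (yhat[i] - mh)^2
  }
  num / sqrt(dy * dh)
}

# one-vs-rest counts and Eq.-style metrics per class
oracle_class_metrics <- function(truth, pred, labels) {
  out <- list()
  n <- length(truth)
  for (k in labels) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    tn <- n - tp - fp - fn
    out[[k]] <- c(tp = tp, tn = tn, fp = fp, fn = fn,
                  accuracy = (tp + tn) / n,
                  precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                  f1 = if (2 * tp + fp + fn > 0)
                    tp / (tp + (fp + fn) / 2) else NA_real_)
  }
  out
}

# positional encoding by direct elementwise evaluation
oracle_positional_encoding <- function(max_len, d_model, base = 10000) {
  PE <- matrix(0, max_len, d_model)
  for (pos in 0:(max_len - 1)) {
    for (i in 0:(d_model / 2 - 1)) {
      arg <- pos / base^(2 * i / d_model)
      PE[pos + 1, 2 * i + 1] <- sin(arg)
      PE[pos + 1, 2 * i + 2] <- cos(arg)
    }
  }
  PE
}

# amplitude of a frequency component by FFT peak
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  sp <- abs(stats::fft(x))[2:(n %/% 2 + 1)] * 2 / n
  freqs <- (1:(n %/% 2)) * fs / n
  sp[which.min(abs(freqs - f))]
}

# numerical gradient of fn at flat parameter vector
numerical_gradient <- function(fn, x, idx = seq_along(x), eps = 1e-6) {
  g <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    x[i] <- x[i] + eps; lp <- fn(x)
    x[i] <- x[i] - 2 * eps; lm <- fn(x)
    x[i] <- x[i] + eps
    g[j] <- (lp - lm) / (2 * eps)
  }
  g
}

# flatten / relist nested parameter structures (for gradient checks)
params_flatten <- function(p) rapply(p, identity, how = "unlist")

params_relist <- function(flat, skeleton) {
  pos <- 0L
  walk <- function(p) {
    for (nm in names(p)) {
      if (is.list(p[[nm]])) {
        p[[nm]] <- walk(p[[nm]])
      } else {
        n <- length(p[[nm]])
        v <- flat[(pos + 1L):(pos + n)]
        dim(v) <- dim(p[[nm]])
        p[[nm]] <- v
        pos <<- pos + n
      }
    }
    p
  }
  walk(skeleton)
}

# small synthetic epoch-pair set with a learnable structure
tiny_pairs <- function(n = 8, len = 32, ch = 3, seed = 1) {
  set.seed(seed)
  obs <- array(0, c(n, len, ch))
  fut <- array(0, c(n, len, ch))
  for (i in seq_len(n)) {
    ph <- runif(1, 0, 2 * pi)
    t1 <- (0:(len - 1)) / 100
    t2 <- (len:(2 * len - 1)) / 100
    for (c in seq_len(ch)) {
      obs[i, , c] <- sin(2 * pi * 3 * t1 + ph + c)
      fut[i, , c] <- sin(2 * pi * 3 * t2 + ph + c)
    }
  }
  structure(list(observed = obs, future = fut,
                 label = rep("walk", n)), class = "hap_pairs")
}
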
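// Recurrent kernels. All batch tensors are Armadillo cubes laid out as
// (batch, feature, time); gate blocks along columns are ordered i, f, o, g.
// The cache cube G additionally stores tanh(c) as a fifth block so the
// backward pass never recomputes transcendentals.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& X, const arma::mat& W, const arma::rowvec& b,
                            const arma::mat& h0, const arma::mat& c0) {
  const uword B = X.n_rows, d = X.n_cols, T = X.n_slices;
  const uword H = W.n_cols / 4;
  // fill R-allocated arrays in place so returning makes no copy
  Rcpp::NumericVector Hv(Rcpp::Dimension(B, H, T)), Cv(Rcpp::Dimension(B, H, T));
  Rcpp::NumericVector Gv(Rcpp::Dimension(B, 5 * H, T));
  cube Hs(Hv.begin(), B, H, T, false, true);
  cube Cs(Cv.begin(), B, H, T, false, true);
  cube G(Gv.begin(), B, 5 * H, T, false, true);
  mat h = h0, c = c0, Z(B, d + H);
  for (uword t = 0; t < T; ++t) {
    Z.cols(0, d - 1) = X.slice(t);
    Z.cols(d, d + H - 1) = h;
    mat A = Z * W;
    A.each_row() += b;
    mat i = 1.0 / (1.0 + exp(-A.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-A.cols(H, 2 * H - 1)));
    mat o = 1.0 / (1.0 + exp(-A.cols(2 * H, 3 * H - 1)));
    mat g = tanh(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    Hs.slice(t) = h;
    Cs.slice(t) = c;
    G.slice(t).cols(0, H - 1) = i;
    G.slice(t).cols(H, 2 * H - 1) = f;
    G.slice(t).cols(2 * H, 3 * H - 1) = o;
    G.slice(t).cols(3 * H, 4 * H - 1) = g;
    G.slice(t).cols(4 * H, 5 * H - 1) = tc;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hv, Rcpp::Named("C") = Cv,
                            Rcpp::Named("G") = Gv);
}

// Backprop through time. dH carries the per-step output gradients;
// dh_last/dc_last the gradient arriving at the final hidden/cell state
// (used when only the final state feeds downstream layers).
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& dH, const arma::mat& dh_last,
                             const arma::mat& dc_last, const arma::cube& X, const arma::mat& W,
                             const arma::cube& Hs, const arma::cube& Cs, const arma::cube& G,
                             const arma::mat& h0, const arma::mat& c0) {
  const uword B = X.n_rows, d = X.n_cols, T = X.n_slices;
  const uword H = W.n_cols / 4;
  cube dX(B, d, T, fill::zeros);
  mat dW(size(W), fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh = dh_last, dc = dc_last, Z(B, d + H);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    mat i = G.slice(t).cols(0, H - 1), f = G.slice(t).cols(H, 2 * H - 1);
    mat o = G.slice(t).cols(2 * H, 3 * H - 1),
        g = G.slice(t).cols(3 * H, 4 * H - 1);
    mat tc = G.slice(t).cols(4 * H, 5 * H - 1);
    mat cprev = (t == 0) ? c0 : Cs.slice(t - 1);
    mat hprev = (t == 0) ? h0 : Hs.slice(t - 1);
    dc += dh % o % (1.0 - tc % tc);
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = dc % g % i % (1.0 - i);
    dA.cols(H, 2 * H - 1) = dc % cprev % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = dh % tc % o % (1.0 - o);
    dA.cols(3 * H, 4 * H - 1) = dc % i % (1.0 - g % g);
    dc = dc % f;
    Z.cols(0, d - 1) = X.slice(t);
    Z.cols(d, d + H - 1) = hprev;
    dW += Z.t() * dA;
    db += sum(dA, 0);
    mat dZ = dA * W.t();
    dX.slice(t) = dZ.cols(0, d - 1);
    dh = dZ.cols(d, d + H - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db, Rcpp::Named("dh0") = dh,
                            Rcpp::Named("dc0") = dc);
}

// Autoregressive decoding for the plain seq2seq forecaster: each step's
// input is [previous output, context Z]; the linear head maps the hidden
// state back to signal channels.
// [[Rcpp::export]]
arma::cube lstm_decode_cpp(const arma::mat& y0, const arma::mat& Z, const arma::mat& W,
                           const arma::rowvec& b, const arma::mat& h0, const arma::mat& c0,
                           const arma::mat& Wout, const arma::rowvec& bout,
                           const int T_out) {
  const uword B = y0.n_rows, nch = y0.n_cols, zd = Z.n_cols;
  const uword H = W.n_cols / 4;
  cube Y(B, nch, (uword)T_out);
  mat h = h0, c = c0, y = y0, Zin(B, nch + zd + H);
  Zin.cols(nch, nch + zd - 1) = Z;
  for (int t = 0; t < T_out; ++t) {
    Zin.cols(0, nch - 1) = y;
    Zin.cols(nch + zd, nch + zd + H - 1) = h;
    mat A = Zin * W;
    A.each_row() += b;
    mat i = 1.0 / (1.0 + exp(-A.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-A.cols(H, 2 * H - 1)));
    mat o = 1.0 / (1.0 + exp(-A.cols(2 * H, 3 * H - 1)));
    mat g = tanh(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    y = h * Wout;
    y.each_row() += bout;
    Y.slice(t) = y;
  }
  return Y;
}

// Row-wise softmax, numerically stabilised.
static mat softmax_rows_arma(const mat& S) {
  mat Z = S.each_col() - max(S, 1);
  Z = exp(Z);
  Z.each_col() /= sum(Z, 1);
  return Z;
}

// Batched multi-head scaled dot-product attention on projected tensors.
// Q, K, V: (T, D, B) cubes; heads split D into contiguous blocks.
// Returns O (T, D, B) and the attention weights A (T, T, B*n_heads).
// [[Rcpp::export]]
Rcpp::List mha_attend_cpp(const arma::cube& Q, const arma::cube& K,
                          const arma::cube& V, const int n_heads) {
  const uword T = Q.n_rows, D = Q.n_cols, B = Q.n_slices;
  const uword nh = (uword)n_heads, dk = D / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  Rcpp::NumericVector Ov(Rcpp::Dimension(T, D, B));
  Rcpp::NumericVector Av(Rcpp::Dimension(T, T, B * nh));
  cube O(Ov.begin(), T, D, B, false, true);
  cube A(Av.begin(), T, T, B * nh, false, true);
  for (uword b = 0; b < B; ++b) {
    for (uword h = 0; h < nh; ++h) {
      const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      mat W = softmax_rows_arma(Q.slice(b).cols(c0, c1) *
                                K.slice(b).cols(c0, c1).t() * scale);
      O.slice(b).cols(c0, c1) = W * V.slice(b).cols(c0, c1);
      A.slice(b * nh + h) = W;
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = Ov, Rcpp::Named("A") = Av);
}

// Backward of mha_attend_cpp. dO: (T, D, B). Returns dQ, dK, dV.
// [[Rcpp::export]]
Rcpp::List mha_attend_bwd_cpp(const arma::cube& dO, const arma::cube& Q,
                              const arma::cube& K, const arma::cube& V,
                              const arma::cube& A, const int n_heads) {
  const uword T = Q.n_rows, D = Q.n_cols, B = Q.n_slices;
  const uword nh = (uword)n_heads, dk = D / nh;
  const double scale = 1.0 / std::sqrt((double)dk);
  Rcpp::NumericVector dQv(Rcpp::Dimension(T, D, B)), dKv(Rcpp::Dimension(T, D, B)), dVv(Rcpp::Dimension(T, D, B));
  cube dQ(dQv.begin(), T, D, B, false, true);
  cube dK(dKv.begin(), T, D, B, false, true);
  cube dV(dVv.begin(), T, D, B, false, true);
  for (uword b = 0; b < B; ++b) {
    for (uword h = 0; h < nh; ++h) {
      const uword c0 = h * dk, c1 = (h + 1) * dk - 1;
      const mat& W = A.slice(b * nh + h);
      mat dOh = dO.slice(b).cols(c0, c1);
      dV.slice(b).cols(c0, c1) = W.t() * dOh;
      mat dA = dOh * V.slice(b).cols(c0, c1).t();
      mat dS = W % (dA.each_col() - sum(dA % W, 1));
      dS *= scale;
      dQ.slice(b).cols(c0, c1) = dS * K.slice(b).cols(c0, c1);
      dK.slice(b).cols(c0, c1) = dS.t() * Q.slice(b).cols(c0, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQv, Rcpp::Named("dK") = dKv,
                            Rcpp::Named("dV") = dVv);
}

// Scheduled-sampling rollout for the seq2seq decoder: at each step the
// realized input is the teacher value where usetf is 1, otherwise the
// model's own previous prediction. Returns the realized input sequence.
// [[Rcpp::export]]
Rcpp::NumericVector lstm_scheduled_rollout_cpp(const arma::cube& Yteacher,
                                      const arma::mat& usetf,
                                      const arma::mat& Z, const arma::mat& W,
                                      const arma::rowvec& b,
                                      const arma::mat& h0, const arma::mat& c0,
                                      const arma::mat& Wout,
                                      const arma::rowvec& bout) {
  const uword B = Yteacher.n_rows, nch = Yteacher.n_cols,
              T = Yteacher.n_slices, zd = Z.n_cols;
  const uword H = W.n_cols / 4;
  Rcpp::NumericVector Rv(Rcpp::Dimension(B, nch, T));
  cube Rin(Rv.begin(), B, nch, T, false, true);
  mat h = h0, c = c0, yown(B, nch, fill::zeros), Zin(B, nch + zd + H);
  Zin.cols(nch, nch + zd - 1) = Z;
  for (uword t = 0; t < T; ++t) {
    mat yin = Yteacher.slice(t);
    if (t > 0) {
      for (uword r = 0; r < B; ++r)
        if (usetf(r, t) < 0.5) yin.row(r) = yown.row(r);
    }
    Rin.slice(t) = yin;
    Zin.cols(0, nch - 1) = yin;
    Zin.cols(nch + zd, nch + zd + H - 1) = h;
    mat A = Zin * W;
    A.each_row() += b;
    mat i = 1.0 / (1.0 + exp(-A.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-A.cols(H, 2 * H - 1)));
    mat o = 1.0 / (1.0 + exp(-A.cols(2 * H, 3 * H - 1)));
    mat g = tanh(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    yown = h * Wout;
    yown.each_row() += bout;
  }
  return Rv;
}

// Autoregressive decoder forward WITH caches, for training the seq2seq
// decoder through its own feedback loop. Input at step t is
// [y_{t-1}, Z, h_{t-1}]; y_0 is the start token.
// [[Rcpp::export]]
Rcpp::List lstm_ar_forward_cpp(const arma::mat& y0, const arma::mat& Z,
                               const arma::mat& W, const arma::rowvec& b,
                               const arma::mat& h0, const arma::mat& c0,
                               const arma::mat& Wout,
                               const arma::rowvec& bout, const int T_out) {
  const uword B = y0.n_rows, nch = y0.n_cols, zd = Z.n_cols;
  const uword H = W.n_cols / 4, T = (uword)T_out;
  Rcpp::NumericVector Yv(Rcpp::Dimension(B, nch, T)),
      Yinv(Rcpp::Dimension(B, nch, T)), Hv(Rcpp::Dimension(B, H, T)),
      Cv(Rcpp::Dimension(B, H, T)), Gv(Rcpp::Dimension(B, 5 * H, T));
  cube Y(Yv.begin(), B, nch, T, false, true);
  cube Yin(Yinv.begin(), B, nch, T, false, true);
  cube Hs(Hv.begin(), B, H, T, false, true);
  cube Cs(Cv.begin(), B, H, T, false, true);
  cube G(Gv.begin(), B, 5 * H, T, false, true);
  mat h = h0, c = c0, y = y0, Zin(B, nch + zd + H);
  Zin.cols(nch, nch + zd - 1) = Z;
  for (uword t = 0; t < T; ++t) {
    Yin.slice(t) = y;
    Zin.cols(0, nch - 1) = y;
    Zin.cols(nch + zd, nch + zd + H - 1) = h;
    mat A = Zin * W;
    A.each_row() += b;
    mat i = 1.0 / (1.0 + exp(-A.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-A.cols(H, 2 * H - 1)));
    mat o = 1.0 / (1.0 + exp(-A.cols(2 * H, 3 * H - 1)));
    mat g = tanh(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    y = h * Wout;
    y.each_row() += bout;
    Y.slice(t) = y;
    Hs.slice(t) = h;
    Cs.slice(t) = c;
    G.slice(t).cols(0, H - 1) = i;
    G.slice(t).cols(H, 2 * H - 1) = f;
    G.slice(t).cols(2 * H, 3 * H - 1) = o;
    G.slice(t).cols(3 * H, 4 * H - 1) = g;
    G.slice(t).cols(4 * H, 5 * H - 1) = tc;
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Yv, Rcpp::Named("Yin") = Yinv,
                            Rcpp::Named("H") = Hv, Rcpp::Named("C") = Cv,
                            Rcpp::Named("G") = Gv);
}

// Backprop through the autoregressive rollout, including the feedback path
// from each prediction into the next step's input.
// [[Rcpp::export]]
Rcpp::List lstm_ar_backward_cpp(const arma::cube& dY, const arma::cube& Yin,
                                const arma::mat& Z, const arma::mat& W,
                                const arma::mat& Wout, const arma::cube& Hs,
                                const arma::cube& Cs, const arma::cube& G,
                                const arma::mat& h0, const arma::mat& c0) {
  const uword B = Yin.n_rows, nch = Yin.n_cols, T = Yin.n_slices;
  const uword zd = Z.n_cols, H = W.n_cols / 4;
  mat dW(size(W), fill::zeros), dWout(size(Wout), fill::zeros);
  rowvec db(4 * H, fill::zeros), dbout(Wout.n_cols, fill::zeros);
  mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
  mat dyfb(B, nch, fill::zeros), dZacc(B, zd, fill::zeros);
  mat Zin(B, nch + zd + H);
  Zin.cols(nch, nch + zd - 1) = Z;
  for (uword t = T; t-- > 0;) {
    mat dy = dY.slice(t) + dyfb;
    dWout += Hs.slice(t).t() * dy;
    dbout += sum(dy, 0);
    dh += dy * Wout.t();
    mat i = G.slice(t).cols(0, H - 1), f = G.slice(t).cols(H, 2 * H - 1);
    mat o = G.slice(t).cols(2 * H, 3 * H - 1),
        g = G.slice(t).cols(3 * H, 4 * H - 1);
    mat tc = G.slice(t).cols(4 * H, 5 * H - 1);
    mat cprev = (t == 0) ? c0 : Cs.slice(t - 1);
    mat hprev = (t == 0) ? h0 : Hs.slice(t - 1);
    dc += dh % o % (1.0 - tc % tc);
    mat dA(B, 4 * H);
    dA.cols(0, H - 1) = dc % g % i % (1.0 - i);
    dA.cols(H, 2 * H - 1) = dc % cprev % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = dh % tc % o % (1.0 - o);
    dA.cols(3 * H, 4 * H - 1) = dc % i % (1.0 - g % g);
    dc = dc % f;
    Zin.cols(0, nch - 1) = Yin.slice(t);
    Zin.cols(nch + zd, nch + zd + H - 1) = hprev;
    dW += Zin.t() * dA;
    db += sum(dA, 0);
    mat dZin = dA * W.t();
    dyfb = dZin.cols(0, nch - 1);
    dZacc += dZin.cols(nch, nch + zd - 1);
    dh = dZin.cols(nch + zd, nch + zd + H - 1);
  }
  return Rcpp::List::create(
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
      Rcpp::Named("dWout") = dWout, Rcpp::Named("dbout") = dbout,
      Rcpp::Named("dZ") = dZacc, Rcpp::Named("dh0") = dh,
      Rcpp::Named("dc0") = dc);
}
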
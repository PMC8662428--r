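// Stacked-LSTM forward pass and backpropagation-through-time.
//
// Layout conventions:
//   X is a cube with dimensions (batch B, channels, time T); slice t is the
//   B x channels input at step t.
//   Gate weights are packed column-wise in the order [input, forget,
//   candidate, output], each block H columns wide, so Wx is (in x 4H),
//   Wh is (H x 4H) and b is length 4H.
//   Recurrent dropout uses one mask per sequence (variational dropout on the
//   hidden state entering the recurrent matmul); masks are drawn in R so all
//   randomness lives in R's RNG.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) {
  return 1.0 / (1.0 + exp(-x));
}

struct LayerCache {
  cube I, F, G, O, C, H;
};

static void layer_forward(const cube& X, const mat& Wx, const mat& Wh,
                          const rowvec& b, const mat& rmask, bool training,
                          LayerCache& cc) {
  const uword T = X.n_slices, B = X.n_rows, Hn = Wh.n_rows;
  cc.I.set_size(B, Hn, T); cc.F.set_size(B, Hn, T); cc.G.set_size(B, Hn, T);
  cc.O.set_size(B, Hn, T); cc.C.set_size(B, Hn, T); cc.H.set_size(B, Hn, T);
  mat h(B, Hn, fill::zeros), c(B, Hn, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat hd = training ? mat(h % rmask) : h;
    mat Z = X.slice(t) * Wx + hd * Wh;
    Z.each_row() += b;
    mat i = sigm(Z.cols(0, Hn - 1));
    mat f = sigm(Z.cols(Hn, 2 * Hn - 1));
    mat g = tanh(Z.cols(2 * Hn, 3 * Hn - 1));
    mat o = sigm(Z.cols(3 * Hn, 4 * Hn - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
    cc.O.slice(t) = o; cc.C.slice(t) = c; cc.H.slice(t) = h;
  }
}

// dHext holds dLoss/dh_t coming from layers above (full cube); for the top
// recurrent layer only the last slice is nonzero.  Accumulates weight
// gradients; optionally returns dLoss/dX for the layer below.
static void layer_backward(const cube& X, const mat& Wx, const mat& Wh,
                           const mat& rmask, bool training,
                           const LayerCache& cc, const cube& dHext,
                           mat& dWx, mat& dWh, rowvec& db,
                           cube& dX, bool want_dx) {
  const uword T = X.n_slices, B = X.n_rows, Hn = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Hn, 4 * Hn);
  db.zeros(4 * Hn);
  if (want_dx) dX.set_size(B, X.n_cols, T);
  mat dh_next(B, Hn, fill::zeros), dc_next(B, Hn, fill::zeros);
  mat zero(B, Hn, fill::zeros);
  for (uword s = T; s-- > 0;) {
    const mat& I = cc.I.slice(s); const mat& F = cc.F.slice(s);
    const mat& G = cc.G.slice(s); const mat& O = cc.O.slice(s);
    mat tc = tanh(cc.C.slice(s));
    mat dh = dHext.slice(s) + dh_next;
    mat do_ = dh % tc;
    mat dc = dc_next + dh % O % (1.0 - tc % tc);
    const mat& cprev = (s == 0) ? zero : cc.C.slice(s - 1);
    mat dZ(B, 4 * Hn);
    dZ.cols(0, Hn - 1)          = (dc % G) % I % (1.0 - I);
    dZ.cols(Hn, 2 * Hn - 1)     = (dc % cprev) % F % (1.0 - F);
    dZ.cols(2 * Hn, 3 * Hn - 1) = (dc % I) % (1.0 - G % G);
    dZ.cols(3 * Hn, 4 * Hn - 1) = do_ % O % (1.0 - O);
    const mat& hprev = (s == 0) ? zero : cc.H.slice(s - 1);
    mat hd = training ? mat(hprev % rmask) : hprev;
    dWx += X.slice(s).t() * dZ;
    dWh += hd.t() * dZ;
    db  += sum(dZ, 0);
    mat dhprev = dZ * Wh.t();
    if (training) dhprev %= rmask;
    dh_next = dhprev;
    dc_next = dc % F;
    if (want_dx) dX.slice(s) = dZ * Wx.t();
  }
}

static mat softmax_rows(mat logits) {
  logits.each_col() -= max(logits, 1);
  mat e = exp(logits);
  e.each_col() /= sum(e, 1);
  return e;
}

// Forward through both recurrent layers + dense softmax head (inference:
// dropout disabled).  Returns B x n class-probability matrix.
// [[Rcpp::export]]
arma::mat cpp_lstm_predict(Rcpp::List params, const arma::cube& X) {
  mat Wx1 = params["Wx1"], Wh1 = params["Wh1"];
  mat Wx2 = params["Wx2"], Wh2 = params["Wh2"];
  rowvec b1 = params["b1"], b2 = params["b2"], bd = params["bd"];
  mat Wd = params["Wd"];
  mat dummy;
  LayerCache c1, c2;
  layer_forward(X, Wx1, Wh1, b1, dummy, false, c1);
  layer_forward(c1.H, Wx2, Wh2, b2, dummy, false, c2);
  mat h2 = c2.H.slice(X.n_slices - 1);
  mat logits = h2 * Wd;
  logits.each_row() += bd;
  return softmax_rows(logits);
}

// One training batch: forward with dropout masks, mean categorical
// cross-entropy over the batch, full BPTT gradients for every parameter.
// y holds 0-based class indices.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_grad(Rcpp::List params, const arma::cube& X,
                         const arma::uvec& y, const arma::mat& rmask1,
                         const arma::mat& rmask2, const arma::mat& dmask) {
  mat Wx1 = params["Wx1"], Wh1 = params["Wh1"];
  mat Wx2 = params["Wx2"], Wh2 = params["Wh2"];
  rowvec b1 = params["b1"], b2 = params["b2"], bd = params["bd"];
  mat Wd = params["Wd"];
  const uword B = X.n_rows, T = X.n_slices, n = Wd.n_cols;

  LayerCache c1, c2;
  layer_forward(X, Wx1, Wh1, b1, rmask1, true, c1);
  layer_forward(c1.H, Wx2, Wh2, b2, rmask2, true, c2);
  mat h2 = c2.H.slice(T - 1);
  mat hdrop = h2 % dmask;
  mat logits = hdrop * Wd;
  logits.each_row() += bd;
  mat P = softmax_rows(logits);

  double loss = 0.0;
  uword correct = 0;
  for (uword b = 0; b < B; ++b) {
    loss -= std::log(std::max(P(b, y(b)), 1e-12));
    if (P.row(b).index_max() == y(b)) ++correct;
  }
  loss /= B;

  mat dLogits = P;
  for (uword b = 0; b < B; ++b) dLogits(b, y(b)) -= 1.0;
  dLogits /= (double)B;

  mat dWd = hdrop.t() * dLogits;
  rowvec dbd = sum(dLogits, 0);
  mat dh2 = (dLogits * Wd.t()) % dmask;

  cube dHext2(B, Wh2.n_rows, T, fill::zeros);
  dHext2.slice(T - 1) = dh2;
  mat dWx2, dWh2g, dWx1, dWh1g;
  rowvec db2, db1;
  cube dX2, dX1;
  layer_backward(c1.H, Wx2, Wh2, rmask2, true, c2, dHext2,
                 dWx2, dWh2g, db2, dX2, true);
  layer_backward(X, Wx1, Wh1, rmask1, true, c1, dX2,
                 dWx1, dWh1g, db1, dX1, false);

  return Rcpp::List::create(
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wx1") = dWx1, Rcpp::Named("Wh1") = dWh1g,
      Rcpp::Named("b1") = db1,
      Rcpp::Named("Wx2") = dWx2, Rcpp::Named("Wh2") = dWh2g,
      Rcpp::Named("b2") = db2,
      Rcpp::Named("Wd") = dWd, Rcpp::Named("bd") = dbd),
    Rcpp::Named("loss") = loss,
    Rcpp::Named("accuracy") = (double)correct / (double)B,
    Rcpp::Named("n") = (double)n);
}
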
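// Minimal sequence-network kernels: embedding lookup, same-padded Conv1D,
// bidirectional LSTM with full BPTT, and global max pooling over time.
// Activations are arma::cube with dims (batch, channels, time) so each
// time step is a contiguous (batch x channels) slice.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---- embedding -------------------------------------------------------------

// [[Rcpp::export]]
arma::cube nn_embed_fwd(const arma::imat& idx, const arma::mat& W) {
  const uword B = idx.n_rows, L = idx.n_cols, d = W.n_cols;
  cube out(B, d, L);
  for (uword t = 0; t < L; ++t)
    for (uword b = 0; b < B; ++b)
      out.slice(t).row(b) = W.row((uword)idx(b, t));
  return out;
}

// [[Rcpp::export]]
arma::mat nn_embed_bwd(const arma::imat& idx, const arma::cube& dOut,
                       const int vocab) {
  const uword B = idx.n_rows, L = idx.n_cols, d = dOut.n_cols;
  mat dW(vocab, d, fill::zeros);
  for (uword t = 0; t < L; ++t)
    for (uword b = 0; b < B; ++b)
      dW.row((uword)idx(b, t)) += dOut.slice(t).row(b);
  return dW;
}

// ---- conv1d (same padding, odd kernel) -------------------------------------

static cube pad_time(const cube& X, const uword pad) {
  cube Xp(X.n_rows, X.n_cols, X.n_slices + 2 * pad, fill::zeros);
  for (uword t = 0; t < X.n_slices; ++t) Xp.slice(t + pad) = X.slice(t);
  return Xp;
}

// im2col over the whole batch-time grid so the convolution is one large GEMM
static mat conv_im2col(const cube& Xp, const uword k, const uword L) {
  const uword B = Xp.n_rows, Cin = Xp.n_cols;
  mat M(B * L, k * Cin);
  for (uword t = 0; t < L; ++t)
    for (uword j = 0; j < k; ++j)
      M.submat(t * B, j * Cin, (t + 1) * B - 1, (j + 1) * Cin - 1) =
          Xp.slice(t + j);
  return M;
}

static cube conv_pre(const cube& Xp, const mat& W, const rowvec& b,
                     const uword k, const uword L) {
  const uword B = Xp.n_rows, F = W.n_cols;
  mat pre_all = conv_im2col(Xp, k, L) * W;   // (B*L) x F
  pre_all.each_row() += b;
  cube pre(B, F, L);
  for (uword t = 0; t < L; ++t)
    pre.slice(t) = pre_all.rows(t * B, (t + 1) * B - 1);
  return pre;
}

// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube& X, const arma::mat& W,
                       const arma::rowvec& b, const int kernel,
                       const bool relu) {
  const uword k = (uword)kernel, pad = (k - 1) / 2;
  cube pre = conv_pre(pad_time(X, pad), W, b, k, X.n_slices);
  if (relu) pre = clamp(pre, 0.0, datum::inf);
  return pre;
}

// Backward pass recomputes the pre-activation internally (cheaper than
// shuttling the cache through R).
// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube& X, const arma::mat& W,
                       const arma::rowvec& b, const arma::cube& dOut,
                       const int kernel, const bool relu) {
  const uword B = X.n_rows, Cin = X.n_cols, L = X.n_slices;
  const uword k = (uword)kernel, pad = (k - 1) / 2, F = W.n_cols;
  cube Xp = pad_time(X, pad);
  cube pre;
  if (relu) pre = conv_pre(Xp, W, b, k, L);
  mat dY_all(B * L, F);
  for (uword t = 0; t < L; ++t) {
    mat dY = dOut.slice(t);
    if (relu) dY %= conv_to<mat>::from(pre.slice(t) > 0.0);
    dY_all.rows(t * B, (t + 1) * B - 1) = dY;
  }
  mat M = conv_im2col(Xp, k, L);
  mat dW = M.t() * dY_all;
  rowvec db = sum(dY_all, 0);
  mat dwin_all = dY_all * W.t();         // (B*L) x (k*Cin)
  cube dXp(B, Cin, L + 2 * pad, fill::zeros);
  for (uword t = 0; t < L; ++t)
    for (uword j = 0; j < k; ++j)
      dXp.slice(t + j) +=
          dwin_all.submat(t * B, j * Cin, (t + 1) * B - 1, (j + 1) * Cin - 1);
  cube dX(B, Cin, L);
  for (uword t = 0; t < L; ++t) dX.slice(t) = dXp.slice(t + pad);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// ---- LSTM (single direction helpers; gate order i, f, g, o) ----------------

struct LstmCache {
  cube I, Fg, G, O, C, H;
};

// stack the time slices of a (B, C, L) cube into a (B*L) x C matrix so the
// input projection X * Wx becomes a single large GEMM
static mat stack_time(const cube& X) {
  const uword B = X.n_rows, C = X.n_cols, L = X.n_slices;
  mat M(B * L, C);
  for (uword t = 0; t < L; ++t)
    M.rows(t * B, (t + 1) * B - 1) = X.slice(t);
  return M;
}

static void lstm_dir_fwd(const mat& Gx_all, const mat& Wh, const rowvec& b,
                         const bool reverse, const uword B, const uword L,
                         LstmCache& cc) {
  const uword u = Wh.n_rows;
  cc.I.set_size(B, u, L); cc.Fg.set_size(B, u, L); cc.G.set_size(B, u, L);
  cc.O.set_size(B, u, L); cc.C.set_size(B, u, L); cc.H.set_size(B, u, L);
  mat h(B, u, fill::zeros), c(B, u, fill::zeros);
  for (uword s = 0; s < L; ++s) {
    const uword t = reverse ? (L - 1 - s) : s;
    mat Gall = Gx_all.rows(t * B, (t + 1) * B - 1) + h * Wh;
    Gall.each_row() += b;
    mat i = 1.0 / (1.0 + exp(-Gall.cols(0, u - 1)));
    mat f = 1.0 / (1.0 + exp(-Gall.cols(u, 2 * u - 1)));
    mat g = tanh(Gall.cols(2 * u, 3 * u - 1));
    mat o = 1.0 / (1.0 + exp(-Gall.cols(3 * u, 4 * u - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    cc.I.slice(t) = i; cc.Fg.slice(t) = f; cc.G.slice(t) = g;
    cc.O.slice(t) = o; cc.C.slice(t) = c; cc.H.slice(t) = h;
  }
}

static void lstm_dir_bwd(const mat& X_all, const mat& Wx, const mat& Wh,
                         const bool reverse, const LstmCache& cc,
                         const cube& dH_out, mat& dX_all, mat& dWx, mat& dWh,
                         rowvec& db) {
  const uword L = cc.H.n_slices, u = Wh.n_rows, B = cc.H.n_rows;
  dWh.zeros(u, 4 * u);
  db.zeros(4 * u);
  mat dG_all(B * L, 4 * u);
  mat dh_next(B, u, fill::zeros), dc_next(B, u, fill::zeros);
  for (uword s = 0; s < L; ++s) {
    // walk time in the opposite order of the forward pass
    const uword t = reverse ? s : (L - 1 - s);
    const bool first = reverse ? (t == L - 1) : (t == 0);
    const uword tprev = reverse ? (t + 1) : (t - 1);
    const mat& i = cc.I.slice(t); const mat& f = cc.Fg.slice(t);
    const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
    mat cprev = first ? mat(B, u, fill::zeros) : cc.C.slice(tprev);
    mat hprev = first ? mat(B, u, fill::zeros) : cc.H.slice(tprev);
    mat tc = tanh(cc.C.slice(t));
    mat dh = dH_out.slice(t) + dh_next;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat dGall(B, 4 * u);
    dGall.cols(0, u - 1)         = dc % g % i % (1.0 - i);
    dGall.cols(u, 2 * u - 1)     = dc % cprev % f % (1.0 - f);
    dGall.cols(2 * u, 3 * u - 1) = dc % i % (1.0 - g % g);
    dGall.cols(3 * u, 4 * u - 1) = dh % tc % o % (1.0 - o);
    dWh += hprev.t() * dGall;
    db += sum(dGall, 0);
    dG_all.rows(t * B, (t + 1) * B - 1) = dGall;
    dh_next = dGall * Wh.t();
    dc_next = dc % f;
  }
  dWx = X_all.t() * dG_all;      // one GEMM each instead of L small ones
  dX_all += dG_all * Wx.t();
}

// [[Rcpp::export]]
arma::cube nn_bilstm_fwd(const arma::cube& X, const arma::mat& Wxf,
                         const arma::mat& Whf, const arma::rowvec& bf,
                         const arma::mat& Wxb, const arma::mat& Whb,
                         const arma::rowvec& bb) {
  const uword B = X.n_rows, L = X.n_slices, u = Whf.n_rows;
  mat X_all = stack_time(X);
  LstmCache cf, cb;
  lstm_dir_fwd(X_all * Wxf, Whf, bf, false, B, L, cf);
  lstm_dir_fwd(X_all * Wxb, Whb, bb, true, B, L, cb);
  cube Y(B, 2 * u, L);
  for (uword t = 0; t < L; ++t) {
    Y.slice(t).cols(0, u - 1) = cf.H.slice(t);
    Y.slice(t).cols(u, 2 * u - 1) = cb.H.slice(t);
  }
  return Y;
}

// Backward pass re-runs the (cheap) forward recurrence internally to rebuild
// gate activations and cell states, avoiding any cache transfer through R.
// [[Rcpp::export]]
Rcpp::List nn_bilstm_bwd(const arma::cube& X, const arma::mat& Wxf,
                         const arma::mat& Whf, const arma::rowvec& bf,
                         const arma::mat& Wxb, const arma::mat& Whb,
                         const arma::rowvec& bb, const arma::cube& dY) {
  const uword B = X.n_rows, Cin = X.n_cols, L = X.n_slices, u = Whf.n_rows;
  mat X_all = stack_time(X);
  LstmCache cf, cb;
  lstm_dir_fwd(X_all * Wxf, Whf, bf, false, B, L, cf);
  lstm_dir_fwd(X_all * Wxb, Whb, bb, true, B, L, cb);
  cube dHf(B, u, L), dHb(B, u, L);
  for (uword t = 0; t < L; ++t) {
    dHf.slice(t) = dY.slice(t).cols(0, u - 1);
    dHb.slice(t) = dY.slice(t).cols(u, 2 * u - 1);
  }
  mat dX_all(B * L, Cin, fill::zeros);
  mat dWxf, dWhf, dWxb, dWhb;
  rowvec dbf, dbb;
  lstm_dir_bwd(X_all, Wxf, Whf, false, cf, dHf, dX_all, dWxf, dWhf, dbf);
  lstm_dir_bwd(X_all, Wxb, Whb, true, cb, dHb, dX_all, dWxb, dWhb, dbb);
  cube dX(B, Cin, L);
  for (uword t = 0; t < L; ++t)
    dX.slice(t) = dX_all.rows(t * B, (t + 1) * B - 1);
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX,
      Rcpp::Named("dWxf") = dWxf, Rcpp::Named("dWhf") = dWhf,
      Rcpp::Named("dbf") = dbf,
      Rcpp::Named("dWxb") = dWxb, Rcpp::Named("dWhb") = dWhb,
      Rcpp::Named("dbb") = dbb);
}

// ---- global max pool over time --------------------------------------------

// [[Rcpp::export]]
Rcpp::List nn_gmp_fwd(const arma::cube& X) {
  const uword B = X.n_rows, C = X.n_cols, L = X.n_slices;
  mat Y(B, C);
  umat am(B, C);
  for (uword b = 0; b < B; ++b)
    for (uword c = 0; c < C; ++c) {
      double best = X(b, c, 0); uword bi = 0;
      for (uword t = 1; t < L; ++t)
        if (X(b, c, t) > best) { best = X(b, c, t); bi = t; }
      Y(b, c) = best; am(b, c) = bi;
    }
  return Rcpp::List::create(Rcpp::Named("out") = Y, Rcpp::Named("argmax") = am);
}

// [[Rcpp::export]]
arma::cube nn_gmp_bwd(const arma::umat& argmax, const arma::mat& dY,
                      const int L) {
  const uword B = dY.n_rows, C = dY.n_cols;
  cube dX(B, C, (uword)L, fill::zeros);
  for (uword b = 0; b < B; ++b)
    for (uword c = 0; c < C; ++c)
      dX(b, c, argmax(b, c)) = dY(b, c);
  return dX;
}

// ---- greedy identity redundancy filter -------------------------------------

// tokens: N x L integer matrix; keep fragment i iff identity to every
// previously kept fragment is <= cutoff. Identity = shared positions / L.
// [[Rcpp::export]]
Rcpp::LogicalVector nn_greedy_filter(const arma::imat& tokens,
                                     const double cutoff) {
  const uword N = tokens.n_rows, L = tokens.n_cols;
  Rcpp::LogicalVector keep(N);
  std::vector<uword> kept;
  kept.reserve(N);
  const uword maxmatch = (uword)std::floor(cutoff * (double)L + 1e-9);
  for (uword i = 0; i < N; ++i) {
    bool ok = true;
    for (uword j = 0; j < kept.size() && ok; ++j) {
      uword m = 0;
      const uword r = kept[j];
      for (uword p = 0; p < L; ++p)
        if (tokens(i, p) == tokens(r, p)) ++m;
      if (m > maxmatch) ok = false;
    }
    keep[i] = ok;
    if (ok) kept.push_back(i);
  }
  return keep;
}
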
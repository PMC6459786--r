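// 1-D convolution and max-pooling kernels for the segment classifier.
// Layout: activations are cubes (channels x time x batch); convolution
// weights are (out_channels x in_channels*kernel) with column index
// k*Cin + cin for kernel offset k and input channel cin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const arma::mat& x, int K, int pad, arma::mat& col) {
  const int Cin = x.n_rows, T = x.n_cols;
  col.zeros();
  for (int k = 0; k < K; ++k) {
    int off = k - pad;
    int t0 = std::max(0, -off);
    int t1 = std::min(T, T - off);
    if (t1 > t0)
      col.rows(k * Cin, (k + 1) * Cin - 1).cols(t0, t1 - 1) =
        x.cols(t0 + off, t1 - 1 + off);
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fw(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b, int K) {
  const int Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows;
  const int pad = (K - 1) / 2;
  arma::cube Y(Cout, T, B);
  arma::mat col(Cin * K, T);
  for (int s = 0; s < B; ++s) {
    im2col(X.slice(s), K, pad, col);
    arma::mat y = W * col;
    y.each_col() += b;
    Y.slice(s) = y;
  }
  return Y;
}

// [[Rcpp::export]]
List conv1d_bw(const arma::cube& X, const arma::mat& W,
               const arma::cube& dY, int K) {
  const int Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int Cout = W.n_rows;
  const int pad = (K - 1) / 2;
  arma::cube dX(Cin, T, B, arma::fill::zeros);
  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(Cin * K, T);
  for (int s = 0; s < B; ++s) {
    im2col(X.slice(s), K, pad, col);
    const arma::mat& dy = dY.slice(s);
    dW += dy * col.t();
    db += arma::sum(dy, 1);
    arma::mat dcol = W.t() * dy;   // (Cin*K) x T
    for (int k = 0; k < K; ++k) {
      int off = k - pad;
      int t0 = std::max(0, -off);
      int t1 = std::min(T, T - off);
      if (t1 > t0)
        dX.slice(s).cols(t0 + off, t1 - 1 + off) +=
          dcol.rows(k * Cin, (k + 1) * Cin - 1).cols(t0, t1 - 1);
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}

// Non-overlapping max pooling along time; remainder samples are dropped.
// [[Rcpp::export]]
List maxpool_fw(const arma::cube& X, int p) {
  const int C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int T2 = T / p;
  arma::cube Y(C, T2, B);
  arma::cube idx(C, T2, B);   // 0-based argmax position in the input
  for (int s = 0; s < B; ++s) {
    const arma::mat& x = X.slice(s);
    for (int t = 0; t < T2; ++t) {
      for (int c = 0; c < C; ++c) {
        int best = t * p;
        double bv = x(c, best);
        for (int u = t * p + 1; u < (t + 1) * p; ++u)
          if (x(c, u) > bv) { bv = x(c, u); best = u; }
        Y(c, t, s) = bv;
        idx(c, t, s) = best;
      }
    }
  }
  return List::create(Named("Y") = Y, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bw(const arma::cube& idx, const arma::cube& dY, int T) {
  const int C = dY.n_rows, T2 = dY.n_cols, B = dY.n_slices;
  arma::cube dX(C, T, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < T2; ++t)
      for (int c = 0; c < C; ++c)
        dX(c, (int)idx(c, t, s), s) += dY(c, t, s);
  return dX;
}
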
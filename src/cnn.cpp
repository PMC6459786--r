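// Fused forward/backward pass for the 1-D convolutional classifier.
// One call per minibatch: convolution blocks (conv -> batch norm -> ReLU
// -> max pool), dropout on the flattened features, dense + ReLU, softmax
// output.  Internals run in single precision; parameters and gradients
// cross the R boundary as doubles.
//
// Weight layout: conv W is (Cout x Cin*K), column index k*Cin + cin for
// kernel offset k and input channel cin.  Activations: (channels x time
// x batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;

struct BlockCache {
  fcube Xin;       // block input
  fcube xhat;      // normalised pre-activation
  fvec invsd;
  arma::ucube mask;   // ReLU mask
  arma::ucube poolIdx;
  int Tin;
};

static void im2colF(const fmat& x, int K, int pad, fmat& col) {
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

static fcube convFw(const fcube& X, const fmat& W, const fvec& b, int K) {
  const int Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  fcube Y(W.n_rows, T, B);
  fmat col(Cin * K, T);
  const int pad = (K - 1) / 2;
  for (int s = 0; s < B; ++s) {
    im2colF(X.slice(s), K, pad, col);
    fmat y = W * col;
    y.each_col() += b;
    Y.slice(s) = y;
  }
  return Y;
}

static void convBw(const fcube& X, const fmat& W, const fcube& dY, int K,
                   fcube& dX, fmat& dW, fvec& db, bool needDX) {
  const int Cin = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int pad = (K - 1) / 2;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_rows);
  if (needDX) dX.zeros(Cin, T, B);
  fmat col(Cin * K, T);
  for (int s = 0; s < B; ++s) {
    im2colF(X.slice(s), K, pad, col);
    const fmat& dy = dY.slice(s);
    dW += dy * col.t();
    db += arma::sum(dy, 1);
    if (!needDX) continue;
    fmat dcol = W.t() * dy;
    for (int k = 0; k < K; ++k) {
      int off = k - pad;
      int t0 = std::max(0, -off);
      int t1 = std::min(T, T - off);
      if (t1 > t0)
        dX.slice(s).cols(t0 + off, t1 - 1 + off) +=
          dcol.rows(k * Cin, (k + 1) * Cin - 1).cols(t0, t1 - 1);
    }
  }
}

static fcube asFcube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  fcube out(d[0], d[1], d[2]);
  const double* src = x.begin();
  float* dst = out.memptr();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static fmat asFmat(SEXP m) {
  NumericMatrix mm(m);
  fmat out(mm.nrow(), mm.ncol());
  std::copy(mm.begin(), mm.end(), out.memptr());
  return out;
}

static fvec asFvec(SEXP v) {
  NumericVector vv(v);
  fvec out(vv.size());
  std::copy(vv.begin(), vv.end(), out.memptr());
  return out;
}

static NumericMatrix wrapF(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

static NumericVector wrapFv(const fvec& v) {
  NumericVector out(v.n_elem);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// Forward through the conv blocks.  In training mode batch statistics
// are used and running stats updated in place (std::vector refs).
static fmat blocksForward(const List& params, const IntegerMatrix& blocks,
                          fcube X, bool training, double momentum,
                          std::vector<fvec>& runMean,
                          std::vector<fvec>& runVar,
                          std::vector<BlockCache>* caches) {
  const int nb = blocks.nrow();
  for (int i = 0; i < nb; ++i) {
    const std::string si = std::to_string(i + 1);
    const int K = blocks(i, 1), P = blocks(i, 2);
    fmat W = asFmat(params["conv" + si + "_W"]);
    fvec b = asFvec(params["conv" + si + "_b"]);
    fvec gamma = asFvec(params["bn" + si + "_gamma"]);
    fvec beta = asFvec(params["bn" + si + "_beta"]);
    fcube Z = convFw(X, W, b, K);
    const int C = Z.n_rows, T = Z.n_cols, B = Z.n_slices;
    const float N = (float)T * (float)B;
    fvec mu(C), var(C);
    if (training) {
      mu.zeros(); var.zeros();
      for (int s = 0; s < B; ++s) {
        mu += arma::sum(Z.slice(s), 1);
        var += arma::sum(arma::square(Z.slice(s)), 1);
      }
      mu /= N;
      var = var / N - arma::square(mu);
      var.transform([](float v) { return v < 0 ? 0.0f : v; });
      runMean[i] = (1.0f - (float)momentum) * runMean[i] +
        (float)momentum * mu;
      runVar[i] = (1.0f - (float)momentum) * runVar[i] +
        (float)momentum * var;
    } else {
      mu = runMean[i];
      var = runVar[i];
    }
    fvec invsd = 1.0f / arma::sqrt(var + BN_EPS);
    BlockCache bc;
    if (caches) { bc.Xin = X; bc.Tin = T; }
    // normalise + scale + ReLU, in place per slice
    fcube xhat(C, T, B);
    arma::ucube mask(C, T, B);
    for (int s = 0; s < B; ++s) {
      fmat zs = Z.slice(s);
      zs.each_col() -= mu;
      zs.each_col() %= invsd;
      xhat.slice(s) = zs;
      zs.each_col() %= gamma;
      zs.each_col() += beta;
      mask.slice(s) = zs > 0;
      Z.slice(s) = zs % arma::conv_to<fmat>::from(mask.slice(s));
    }
    // max pool
    const int T2 = T / P;
    fcube Y(C, T2, B);
    arma::ucube idx(C, T2, B);
    for (int s = 0; s < B; ++s) {
      const fmat& zs = Z.slice(s);
      for (int t = 0; t < T2; ++t)
        for (int c = 0; c < C; ++c) {
          int best = t * P;
          float bv = zs(c, best);
          for (int u = t * P + 1; u < (t + 1) * P; ++u)
            if (zs(c, u) > bv) { bv = zs(c, u); best = u; }
          Y(c, t, s) = bv;
          idx(c, t, s) = best;
        }
    }
    if (caches) {
      bc.xhat = std::move(xhat);
      bc.invsd = invsd;
      bc.mask = std::move(mask);
      bc.poolIdx = std::move(idx);
      caches->push_back(std::move(bc));
    }
    X = std::move(Y);
  }
  // flatten: (C*T2) x B
  const int flat = X.n_rows * X.n_cols;
  fmat F(flat, X.n_slices);
  for (arma::uword s = 0; s < X.n_slices; ++s)
    F.col(s) = arma::vectorise(X.slice(s));
  return F;
}

static fmat softmaxCols(const fmat& logits) {
  fmat p = logits;
  for (arma::uword j = 0; j < p.n_cols; ++j) {
    p.col(j) -= p.col(j).max();
    p.col(j) = arma::exp(p.col(j));
    p.col(j) /= arma::accu(p.col(j));
  }
  return p;
}

// Evaluation-mode forward pass: class probabilities (K x B).
// [[Rcpp::export]]
NumericMatrix cnn_eval(const List& params, const List& bnMean,
                       const List& bnVar, const NumericVector& X,
                       const IntegerMatrix& blocks) {
  const int nb = blocks.nrow();
  std::vector<fvec> rm(nb), rv(nb);
  for (int i = 0; i < nb; ++i) {
    rm[i] = asFvec(bnMean[i]);
    rv[i] = asFvec(bnVar[i]);
  }
  fcube Xc = asFcube(X);
  fmat F = blocksForward(params, blocks, std::move(Xc), false, 0.0,
                         rm, rv, nullptr);
  fmat denseW = asFmat(params["dense_W"]);
  fvec denseB = asFvec(params["dense_b"]);
  fmat outW = asFmat(params["out_W"]);
  fvec outB = asFvec(params["out_b"]);
  fmat H = denseW * F;
  H.each_col() += denseB;
  H.transform([](float v) { return v > 0 ? v : 0.0f; });
  fmat logits = outW * H;
  logits.each_col() += outB;
  return wrapF(softmaxCols(logits));
}

// One training step: forward with batch statistics, cross-entropy loss,
// full backward pass.  Returns the mean CE loss, probabilities, gradients
// (without the L2 term, added on the R side) and updated running stats.
// targets are 1-based class indices; dropMask is the inverted-dropout
// mask on the flattened features (flatDim x B), or a 0x0 matrix.
// [[Rcpp::export]]
List cnn_step(const List& params, const List& bnMean, const List& bnVar,
              const NumericVector& X, const IntegerVector& targets,
              const IntegerMatrix& blocks, double momentum,
              const NumericMatrix& dropMask,
              const NumericVector& sampleWeights) {
  const int nb = blocks.nrow();
  std::vector<fvec> rm(nb), rv(nb);
  for (int i = 0; i < nb; ++i) {
    rm[i] = asFvec(bnMean[i]);
    rv[i] = asFvec(bnVar[i]);
  }
  std::vector<BlockCache> caches;
  caches.reserve(nb);
  fcube Xc = asFcube(X);
  fmat F = blocksForward(params, blocks, std::move(Xc), true, momentum,
                         rm, rv, &caches);
  const int B = F.n_cols;
  fmat Fd = F;
  const bool useDrop = dropMask.nrow() > 0;
  fmat dm;
  if (useDrop) {
    dm = asFmat(dropMask);
    Fd %= dm;
  }
  fmat denseW = asFmat(params["dense_W"]);
  fvec denseB = asFvec(params["dense_b"]);
  fmat outW = asFmat(params["out_W"]);
  fvec outB = asFvec(params["out_b"]);
  fmat Hpre = denseW * Fd;
  Hpre.each_col() += denseB;
  fmat H = Hpre;
  H.transform([](float v) { return v > 0 ? v : 0.0f; });
  fmat logits = outW * H;
  logits.each_col() += outB;
  fmat probs = softmaxCols(logits);
  fvec w(B);
  if (sampleWeights.size() == B)
    for (int j = 0; j < B; ++j) w(j) = (float)sampleWeights[j];
  else w.ones();
  const float wsum = arma::accu(w);
  double loss = 0;
  for (int j = 0; j < B; ++j) {
    float p = probs(targets[j] - 1, j);
    loss += -w(j) * std::log(std::max(p, 1e-12f));
  }
  loss /= wsum;
  // backward
  fmat dlogits = probs;
  for (int j = 0; j < B; ++j) {
    dlogits(targets[j] - 1, j) -= 1.0f;
    dlogits.col(j) *= w(j) / wsum;
  }
  List grads;
  grads["out_W"] = wrapF(dlogits * H.t());
  grads["out_b"] = wrapFv(arma::sum(dlogits, 1));
  fmat dH = outW.t() * dlogits;
  dH %= arma::conv_to<fmat>::from(Hpre > 0);
  grads["dense_W"] = wrapF(dH * Fd.t());
  grads["dense_b"] = wrapFv(arma::sum(dH, 1));
  fmat dF = denseW.t() * dH;
  if (useDrop) dF %= dm;
  // un-flatten into the last block's pooled shape
  const int lastC = blocks(nb - 1, 0);
  const int lastT = F.n_rows / lastC;
  fcube dA(lastC, lastT, B);
  for (int s = 0; s < B; ++s)
    dA.slice(s) = arma::reshape(dF.col(s), lastC, lastT);
  for (int i = nb - 1; i >= 0; --i) {
    const std::string si = std::to_string(i + 1);
    const int K = blocks(i, 1);
    BlockCache& bc = caches[i];
    const int C = bc.xhat.n_rows, T = bc.Tin;
    const float N = (float)T * (float)B;
    fvec gamma = asFvec(params["bn" + si + "_gamma"]);
    // pool backward + ReLU mask
    fcube dAct(C, T, B, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      const fmat& das = dA.slice(s);
      for (arma::uword t = 0; t < dA.n_cols; ++t)
        for (int c = 0; c < C; ++c)
          dAct(c, bc.poolIdx(c, t, s), s) += das(c, t);
      dAct.slice(s) %= arma::conv_to<fmat>::from(bc.mask.slice(s));
    }
    // batch-norm backward
    fvec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
    fvec mean_dxhat(C, arma::fill::zeros), mean_dxx(C, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      dgamma += arma::sum(dAct.slice(s) % bc.xhat.slice(s), 1);
      dbeta += arma::sum(dAct.slice(s), 1);
    }
    // dxhat = dAct * gamma (rowwise); accumulate its row means
    for (int s = 0; s < B; ++s) {
      fmat dx = dAct.slice(s);
      dx.each_col() %= gamma;
      dAct.slice(s) = dx;
      mean_dxhat += arma::sum(dx, 1);
      mean_dxx += arma::sum(dx % bc.xhat.slice(s), 1);
    }
    mean_dxhat /= N;
    mean_dxx /= N;
    fcube dZ(C, T, B);
    for (int s = 0; s < B; ++s) {
      fmat t1 = dAct.slice(s);
      t1.each_col() -= mean_dxhat;
      fmat t2 = bc.xhat.slice(s);
      t2.each_col() %= mean_dxx;
      t1 -= t2;
      t1.each_col() %= bc.invsd;
      dZ.slice(s) = t1;
    }
    grads["bn" + si + "_gamma"] = wrapFv(dgamma);
    grads["bn" + si + "_beta"] = wrapFv(dbeta);
    fmat W = asFmat(params["conv" + si + "_W"]);
    fcube dX;
    fmat dW;
    fvec db;
    convBw(bc.Xin, W, dZ, K, dX, dW, db, i > 0);
    grads["conv" + si + "_W"] = wrapF(dW);
    grads["conv" + si + "_b"] = wrapFv(db);
    if (i > 0) dA = std::move(dX);
  }
  List outMean(nb), outVar(nb);
  for (int i = 0; i < nb; ++i) {
    outMean[i] = wrapFv(rm[i]);
    outVar[i] = wrapFv(rv[i]);
  }
  return List::create(Named("loss") = loss,
                      Named("probs") = wrapF(probs),
                      Named("grads") = grads,
                      Named("bnMean") = outMean,
                      Named("bnVar") = outVar);
}
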
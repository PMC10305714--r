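// Compiled numerical core: IIR filtering (direct form II transposed) and the
// 1D CNN used for activity classification (im2col convolutions, batch
// normalisation, max / global-average pooling, softmax cross-entropy).
// All randomness (weight init, shuffling, dropout masks) lives on the R side,
// so these routines are fully deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// IIR filter, direct form II transposed, with explicit initial state.
// [[Rcpp::export]]
arma::vec iir_filter_cpp(const arma::vec& b, const arma::vec& a,
                         const arma::vec& x, const arma::vec& zi) {
  const int n = x.n_elem;
  const int nf = std::max(a.n_elem, b.n_elem);
  arma::vec bb = arma::zeros(nf), aa = arma::zeros(nf);
  bb.head(b.n_elem) = b;
  aa.head(a.n_elem) = a;
  bb /= aa(0);
  aa /= aa(0);
  arma::vec z = arma::zeros(nf - 1);
  if ((int)zi.n_elem == nf - 1) z = zi;
  arma::vec y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x(i);
    const double yi = bb(0) * xi + (nf > 1 ? z(0) : 0.0);
    for (int k = 0; k < nf - 2; ++k)
      z(k) = bb(k + 1) * xi + z(k + 1) - aa(k + 1) * yi;
    if (nf > 1) z(nf - 2) = bb(nf - 1) * xi - aa(nf - 1) * yi;
    y(i) = yi;
  }
  return y;
}

// ---------------------------------------------------------------------------
// CNN building blocks.  Activations are cubes (time x channels x batch).

static arma::mat im2col(const arma::cube& X, int k) {
  const int L = X.n_rows, C = X.n_cols, N = X.n_slices;
  const int Lout = L - k + 1;
  arma::mat M(N * Lout, k * C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < k; ++i)
        M.submat(n * Lout, i + k * c, n * Lout + Lout - 1, i + k * c) =
            X.slice(n).col(c).subvec(i, i + Lout - 1);
  return M;
}

static arma::cube mat_to_cube(const arma::mat& Y, int Lout, int N) {
  arma::cube out(Lout, Y.n_cols, N);
  for (int n = 0; n < N; ++n)
    out.slice(n) = Y.rows(n * Lout, (n + 1) * Lout - 1);
  return out;
}

static arma::mat cube_to_mat(const arma::cube& Y) {
  const int Lout = Y.n_rows, N = Y.n_slices;
  arma::mat M(N * Lout, Y.n_cols);
  for (int n = 0; n < N; ++n)
    M.rows(n * Lout, (n + 1) * Lout - 1) = Y.slice(n);
  return M;
}

struct ConvCache {
  arma::mat M;  // im2col of the layer input
  int L, Lout;
};

static arma::cube conv_forward(const arma::cube& X, const arma::mat& W,
                               const arma::vec& b, ConvCache& cache) {
  const int C = X.n_cols;
  const int k = W.n_rows / C;
  cache.L = X.n_rows;
  cache.Lout = X.n_rows - k + 1;
  cache.M = im2col(X, k);
  arma::mat Y = cache.M * W;
  Y.each_row() += b.t();
  return mat_to_cube(Y, cache.Lout, X.n_slices);
}

static arma::cube conv_backward(const arma::cube& dY, const ConvCache& cache,
                                const arma::mat& W, int C,
                                arma::mat& dW, arma::vec& db) {
  const int k = W.n_rows / C;
  const int N = dY.n_slices, Lout = cache.Lout;
  arma::mat dYm = cube_to_mat(dY);
  dW = cache.M.t() * dYm;
  db = arma::sum(dYm, 0).t();
  arma::mat dM = dYm * W.t();
  arma::cube dX(cache.L, C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < k; ++i)
        dX.slice(n).col(c).subvec(i, i + Lout - 1) +=
            dM.col(i + k * c).subvec(n * Lout, n * Lout + Lout - 1);
  return dX;
}

struct BNCache {
  arma::cube xhat;
  arma::vec invstd;
};

static const double BN_EPS = 1e-5;

static arma::cube bn_forward_train(const arma::cube& X, const arma::vec& gamma,
                                   const arma::vec& beta, arma::vec& rmean,
                                   arma::vec& rvar, double momentum,
                                   BNCache& cache) {
  const int L = X.n_rows, K = X.n_cols, N = X.n_slices;
  const double m = (double)L * N;
  arma::vec mu(K, arma::fill::zeros), var(K, arma::fill::zeros);
  for (int n = 0; n < N; ++n) mu += arma::sum(X.slice(n), 0).t();
  mu /= m;
  for (int n = 0; n < N; ++n) {
    arma::mat d = X.slice(n);
    d.each_row() -= mu.t();
    var += arma::sum(arma::square(d), 0).t();
  }
  var /= m;
  rmean = (1 - momentum) * rmean + momentum * mu;
  rvar = (1 - momentum) * rvar + momentum * var;
  cache.invstd = 1.0 / arma::sqrt(var + BN_EPS);
  cache.xhat.set_size(L, K, N);
  arma::cube Y(L, K, N);
  for (int n = 0; n < N; ++n) {
    arma::mat xh = X.slice(n);
    xh.each_row() -= mu.t();
    xh.each_row() %= cache.invstd.t();
    cache.xhat.slice(n) = xh;
    xh.each_row() %= gamma.t();
    xh.each_row() += beta.t();
    Y.slice(n) = xh;
  }
  return Y;
}

static arma::cube bn_forward_eval(const arma::cube& X, const arma::vec& gamma,
                                  const arma::vec& beta, const arma::vec& rmean,
                                  const arma::vec& rvar) {
  arma::cube Y = X;
  arma::vec invstd = 1.0 / arma::sqrt(rvar + BN_EPS);
  for (arma::uword n = 0; n < X.n_slices; ++n) {
    Y.slice(n).each_row() -= rmean.t();
    Y.slice(n).each_row() %= (invstd % gamma).t();
    Y.slice(n).each_row() += beta.t();
  }
  return Y;
}

static arma::cube bn_backward(const arma::cube& dY, const BNCache& cache,
                              const arma::vec& gamma, arma::vec& dgamma,
                              arma::vec& dbeta) {
  const int L = dY.n_rows, K = dY.n_cols, N = dY.n_slices;
  const double m = (double)L * N;
  dgamma.zeros(K);
  dbeta.zeros(K);
  arma::vec sum_dxhat(K, arma::fill::zeros), sum_dxhat_xhat(K, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    dgamma += arma::sum(dY.slice(n) % cache.xhat.slice(n), 0).t();
    dbeta += arma::sum(dY.slice(n), 0).t();
  }
  // dxhat = dY * gamma
  for (int n = 0; n < N; ++n) {
    arma::mat dxh = dY.slice(n);
    dxh.each_row() %= gamma.t();
    sum_dxhat += arma::sum(dxh, 0).t();
    sum_dxhat_xhat += arma::sum(dxh % cache.xhat.slice(n), 0).t();
  }
  arma::cube dX(L, K, N);
  for (int n = 0; n < N; ++n) {
    arma::mat dxh = dY.slice(n);
    dxh.each_row() %= gamma.t();
    arma::mat t = m * dxh;
    t.each_row() -= sum_dxhat.t();
    t -= cache.xhat.slice(n) % arma::repmat(sum_dxhat_xhat.t(), L, 1);
    t.each_row() %= (cache.invstd / m).t();
    dX.slice(n) = t;
  }
  return dX;
}

static arma::cube maxpool_forward(const arma::cube& X, int pool,
                                  arma::ucube& argmax) {
  const int L = X.n_rows, K = X.n_cols, N = X.n_slices;
  const int Lp = L / pool;
  arma::cube Y(Lp, K, N);
  argmax.set_size(Lp, K, N);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < Lp; ++t) {
        arma::uword rel;
        Y(t, k, n) = X.slice(n).col(k).subvec(t * pool, t * pool + pool - 1)
                         .max(rel);
        argmax(t, k, n) = t * pool + rel;
      }
  return Y;
}

static arma::cube maxpool_backward(const arma::cube& dY, const arma::ucube& argmax,
                                   int L) {
  const int Lp = dY.n_rows, K = dY.n_cols, N = dY.n_slices;
  arma::cube dX(L, K, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k)
      for (int t = 0; t < Lp; ++t)
        dX(argmax(t, k, n), k, n) += dY(t, k, n);
  return dX;
}

static arma::mat gap_forward(const arma::cube& X) {
  arma::mat G(X.n_cols, X.n_slices);
  for (arma::uword n = 0; n < X.n_slices; ++n)
    G.col(n) = arma::mean(X.slice(n), 0).t();
  return G;
}

static arma::mat softmax_cols(const arma::mat& logits) {
  arma::mat P = logits;
  P.each_row() -= arma::max(P, 0);
  P = arma::exp(P);
  P.each_row() /= arma::sum(P, 0);
  return P;
}

// ---------------------------------------------------------------------------
// Whole-network passes.  Architecture (fixed topology, parameterised sizes):
// conv -> BN -> ReLU -> maxpool -> conv -> BN -> ReLU -> conv -> BN -> ReLU
// -> global average pool -> dropout -> dense -> softmax.

// [[Rcpp::export]]
List cpp_cnn_eval(const arma::cube& X, const List& params, const List& running,
                  int pool) {
  ConvCache cc;
  arma::cube A = conv_forward(X, as<arma::mat>(params["W1"]),
                              as<arma::vec>(params["b1"]), cc);
  A = bn_forward_eval(A, as<arma::vec>(params["g1"]), as<arma::vec>(params["be1"]),
                      as<arma::vec>(running["rm1"]), as<arma::vec>(running["rv1"]));
  A.transform([](double v) { return v > 0 ? v : 0; });
  arma::ucube am;
  A = maxpool_forward(A, pool, am);
  A = conv_forward(A, as<arma::mat>(params["W2"]), as<arma::vec>(params["b2"]), cc);
  A = bn_forward_eval(A, as<arma::vec>(params["g2"]), as<arma::vec>(params["be2"]),
                      as<arma::vec>(running["rm2"]), as<arma::vec>(running["rv2"]));
  A.transform([](double v) { return v > 0 ? v : 0; });
  A = conv_forward(A, as<arma::mat>(params["W3"]), as<arma::vec>(params["b3"]), cc);
  A = bn_forward_eval(A, as<arma::vec>(params["g3"]), as<arma::vec>(params["be3"]),
                      as<arma::vec>(running["rm3"]), as<arma::vec>(running["rv3"]));
  A.transform([](double v) { return v > 0 ? v : 0; });
  arma::mat G = gap_forward(A);
  arma::mat Wd = as<arma::mat>(params["Wd"]);
  arma::vec bd = as<arma::vec>(params["bd"]);
  arma::mat logits = Wd.t() * G;
  logits.each_col() += bd;
  return List::create(_["probs"] = softmax_cols(logits), _["features"] = G);
}

// [[Rcpp::export]]
List cpp_cnn_train_step(const arma::cube& X, const arma::mat& Y_onehot,
                        const List& params, const List& running,
                        const arma::mat& dropout_mask, int pool,
                        double momentum) {
  const int C = X.n_cols, N = X.n_slices;
  arma::mat W1 = as<arma::mat>(params["W1"]), W2 = as<arma::mat>(params["W2"]),
            W3 = as<arma::mat>(params["W3"]), Wd = as<arma::mat>(params["Wd"]);
  arma::vec b1 = as<arma::vec>(params["b1"]), b2 = as<arma::vec>(params["b2"]),
            b3 = as<arma::vec>(params["b3"]), bd = as<arma::vec>(params["bd"]);
  arma::vec g1 = as<arma::vec>(params["g1"]), g2 = as<arma::vec>(params["g2"]),
            g3 = as<arma::vec>(params["g3"]);
  arma::vec be1 = as<arma::vec>(params["be1"]), be2 = as<arma::vec>(params["be2"]),
            be3 = as<arma::vec>(params["be3"]);
  arma::vec rm1 = as<arma::vec>(running["rm1"]), rv1 = as<arma::vec>(running["rv1"]),
            rm2 = as<arma::vec>(running["rm2"]), rv2 = as<arma::vec>(running["rv2"]),
            rm3 = as<arma::vec>(running["rm3"]), rv3 = as<arma::vec>(running["rv3"]);

  // forward
  ConvCache cc1, cc2, cc3;
  BNCache bn1, bn2, bn3;
  arma::cube C1 = conv_forward(X, W1, b1, cc1);
  arma::cube B1 = bn_forward_train(C1, g1, be1, rm1, rv1, momentum, bn1);
  arma::cube R1 = B1;
  R1.transform([](double v) { return v > 0 ? v : 0; });
  arma::ucube am1;
  arma::cube P1 = maxpool_forward(R1, pool, am1);
  arma::cube C2 = conv_forward(P1, W2, b2, cc2);
  arma::cube B2 = bn_forward_train(C2, g2, be2, rm2, rv2, momentum, bn2);
  arma::cube R2 = B2;
  R2.transform([](double v) { return v > 0 ? v : 0; });
  arma::cube C3 = conv_forward(R2, W3, b3, cc3);
  arma::cube B3 = bn_forward_train(C3, g3, be3, rm3, rv3, momentum, bn3);
  arma::cube R3 = B3;
  R3.transform([](double v) { return v > 0 ? v : 0; });
  arma::mat G = gap_forward(R3);
  arma::mat G2 = G % dropout_mask;
  arma::mat logits = Wd.t() * G2;
  logits.each_col() += bd;
  arma::mat P = softmax_cols(logits);

  const double eps = 1e-12;
  double loss = -arma::accu(Y_onehot % arma::log(P + eps)) / N;

  // backward
  arma::mat dlogits = (P - Y_onehot) / N;
  arma::vec dbd = arma::sum(dlogits, 1);
  arma::mat dWd = G2 * dlogits.t();
  arma::mat dG = (Wd * dlogits) % dropout_mask;

  const int L3 = R3.n_rows;
  arma::cube dR3(L3, R3.n_cols, N);
  for (int n = 0; n < N; ++n)
    dR3.slice(n) = arma::repmat(dG.col(n).t() / L3, L3, 1);
  for (int n = 0; n < N; ++n)
    dR3.slice(n) %= arma::conv_to<arma::mat>::from(R3.slice(n) > 0);
  arma::vec dg3, dbe3;
  arma::cube dC3 = bn_backward(dR3, bn3, g3, dg3, dbe3);
  arma::mat dW3;
  arma::vec db3;
  arma::cube dR2 = conv_backward(dC3, cc3, W3, R2.n_cols, dW3, db3);
  for (int n = 0; n < N; ++n)
    dR2.slice(n) %= arma::conv_to<arma::mat>::from(R2.slice(n) > 0);
  arma::vec dg2, dbe2;
  arma::cube dC2 = bn_backward(dR2, bn2, g2, dg2, dbe2);
  arma::mat dW2;
  arma::vec db2;
  arma::cube dP1 = conv_backward(dC2, cc2, W2, P1.n_cols, dW2, db2);
  arma::cube dR1 = maxpool_backward(dP1, am1, R1.n_rows);
  for (int n = 0; n < N; ++n)
    dR1.slice(n) %= arma::conv_to<arma::mat>::from(R1.slice(n) > 0);
  arma::vec dg1, dbe1;
  arma::cube dC1 = bn_backward(dR1, bn1, g1, dg1, dbe1);
  arma::mat dW1;
  arma::vec db1;
  conv_backward(dC1, cc1, W1, C, dW1, db1);

  return List::create(
    _["loss"] = loss, _["probs"] = P,
    _["grads"] = List::create(
      _["W1"] = dW1, _["b1"] = db1, _["g1"] = dg1, _["be1"] = dbe1,
      _["W2"] = dW2, _["b2"] = db2, _["g2"] = dg2, _["be2"] = dbe2,
      _["W3"] = dW3, _["b3"] = db3, _["g3"] = dg3, _["be3"] = dbe3,
      _["Wd"] = dWd, _["bd"] = dbd),
    _["running"] = List::create(
      _["rm1"] = rm1, _["rv1"] = rv1, _["rm2"] = rm2, _["rv2"] = rv2,
      _["rm3"] = rm3, _["rv3"] = rv3));
}
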
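#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Single-hidden-layer perceptron (ReLU hidden units, logistic output)
// trained by full-batch Adam on the cross-entropy loss with L2 penalty.
// Weights are initialised from R's RNG, so determinism follows the
// caller's set.seed().  Returns predicted probabilities for Xte.
// [[Rcpp::export]]
NumericVector cpp_mlp_predict(NumericMatrix Xtr, NumericVector ytr,
                              NumericMatrix Xte, int hidden, int epochs,
                              double lr, double l2) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), m = Xte.nrow(), h = hidden;
  const double b1a = 0.9, b2a = 0.999, eps = 1e-8;
  RNGScope scope;
  std::vector<double> W1((size_t)p * h), W2(h), bb1(h, 0.0);
  double bb2 = 0.0;
  const double s1 = std::sqrt(2.0 / p), s2 = std::sqrt(2.0 / h);
  for (size_t t = 0; t < W1.size(); ++t) W1[t] = R::norm_rand() * s1;
  for (int t = 0; t < h; ++t) W2[t] = R::norm_rand() * s2;

  std::vector<double> H((size_t)n * h), dH((size_t)n * h), z(n), pr(n);
  std::vector<double> gW1(W1.size()), gW2(h), gb1(h);
  std::vector<double> mW1(W1.size(), 0), vW1(W1.size(), 0), mW2(h, 0),
      vW2(h, 0), mb1(h, 0), vb1(h, 0);
  double mb2 = 0, vb2 = 0;
  const double one = 1.0, zero = 0.0;
  char N = 'N', T = 'T';

  for (int ep = 1; ep <= epochs; ++ep) {
    // H = relu(Xtr W1 + b1)
    F77_CALL(dgemm)(&N, &N, &n, &h, &p, &one, Xtr.begin(), &n, &W1[0], &p,
                    &zero, &H[0], &n FCONE FCONE);
    for (int j = 0; j < h; ++j)
      for (int i = 0; i < n; ++i) {
        double v = H[i + (size_t)n * j] + bb1[j];
        H[i + (size_t)n * j] = v > 0 ? v : 0;
      }
    // output and gradient dz = (sigmoid(z) - y) / n
    for (int i = 0; i < n; ++i) {
      double acc = bb2;
      for (int j = 0; j < h; ++j) acc += H[i + (size_t)n * j] * W2[j];
      pr[i] = 1.0 / (1.0 + std::exp(-acc));
      z[i] = (pr[i] - ytr[i]) / n;
    }
    double gb2 = 0;
    for (int i = 0; i < n; ++i) gb2 += z[i];
    for (int j = 0; j < h; ++j) {
      double acc = 0;
      for (int i = 0; i < n; ++i) acc += H[i + (size_t)n * j] * z[i];
      gW2[j] = acc + l2 * W2[j];
    }
    // dH = dz W2' masked by relu
    for (int j = 0; j < h; ++j)
      for (int i = 0; i < n; ++i)
        dH[i + (size_t)n * j] =
            H[i + (size_t)n * j] > 0 ? z[i] * W2[j] : 0.0;
    F77_CALL(dgemm)(&T, &N, &p, &h, &n, &one, Xtr.begin(), &n, &dH[0], &n,
                    &zero, &gW1[0], &p FCONE FCONE);
    for (size_t t = 0; t < W1.size(); ++t) gW1[t] += l2 * W1[t];
    for (int j = 0; j < h; ++j) {
      double acc = 0;
      for (int i = 0; i < n; ++i) acc += dH[i + (size_t)n * j];
      gb1[j] = acc;
    }
    // Adam updates
    const double c1 = 1.0 - std::pow(b1a, ep), c2 = 1.0 - std::pow(b2a, ep);
    for (size_t t = 0; t < W1.size(); ++t) {
      mW1[t] = b1a * mW1[t] + (1 - b1a) * gW1[t];
      vW1[t] = b2a * vW1[t] + (1 - b2a) * gW1[t] * gW1[t];
      W1[t] -= lr * (mW1[t] / c1) / (std::sqrt(vW1[t] / c2) + eps);
    }
    for (int j = 0; j < h; ++j) {
      mW2[j] = b1a * mW2[j] + (1 - b1a) * gW2[j];
      vW2[j] = b2a * vW2[j] + (1 - b2a) * gW2[j] * gW2[j];
      W2[j] -= lr * (mW2[j] / c1) / (std::sqrt(vW2[j] / c2) + eps);
      mb1[j] = b1a * mb1[j] + (1 - b1a) * gb1[j];
      vb1[j] = b2a * vb1[j] + (1 - b2a) * gb1[j] * gb1[j];
      bb1[j] -= lr * (mb1[j] / c1) / (std::sqrt(vb1[j] / c2) + eps);
    }
    mb2 = b1a * mb2 + (1 - b1a) * gb2;
    vb2 = b2a * vb2 + (1 - b2a) * gb2 * gb2;
    bb2 -= lr * (mb2 / c1) / (std::sqrt(vb2 / c2) + eps);
  }

  // predictions on the test block
  NumericVector out(m);
  std::vector<double> Ht((size_t)m * h);
  F77_CALL(dgemm)(&N, &N, &m, &h, &p, &one, Xte.begin(), &m, &W1[0], &p,
                  &zero, &Ht[0], &m FCONE FCONE);
  for (int i = 0; i < m; ++i) {
    double acc = bb2;
    for (int j = 0; j < h; ++j) {
      double v = Ht[i + (size_t)m * j] + bb1[j];
      if (v > 0) acc += v * W2[j];
    }
    out[i] = 1.0 / (1.0 + std::exp(-acc));
  }
  return out;
}
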
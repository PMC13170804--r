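// Epsilon-insensitive support-vector regression with an RBF kernel.
//
// Dual formulation with the bias folded into the kernel (K + 1), which
// removes the equality constraint and leaves a box-constrained problem
//   min_b  0.5 b' (K+1) b - y'b + eps * ||b||_1,   b in [-C, C]^n
// solved exactly by cyclic coordinate descent with soft-thresholding.
// Deterministic: no randomness, fixed sweep order.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sq(double v) { return v * v; }

// [[Rcpp::export(name = ".svr_fit")]]
List svr_fit(NumericMatrix X, NumericVector y, double cost, double gamma,
             double epsilon, double tol, int max_sweeps) {
  int n = X.nrow(), p = X.ncol();
  // dense kernel Ktilde = K + 1
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double d2 = 0.0;
      for (int f = 0; f < p; ++f)
        d2 += sq(X[(size_t)f * n + i] - X[(size_t)f * n + j]);
      double v = std::exp(-gamma * d2) + 1.0;
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }
  std::vector<double> beta(n, 0.0), g(n); // g = Ktilde beta - y
  for (int i = 0; i < n; ++i) g[i] = -y[i];

  int sweeps = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double kii = K[(size_t)i * n + i];
      double r = g[i] - kii * beta[i]; // gradient of smooth part at b_i = 0
      double b;
      if (-r - epsilon > 0)      b = (-r - epsilon) / kii;
      else if (-r + epsilon < 0) b = (-r + epsilon) / kii;
      else                       b = 0.0;
      if (b >  cost) b =  cost;
      if (b < -cost) b = -cost;
      double delta = b - beta[i];
      if (std::fabs(delta) > 1e-15) {
        beta[i] = b;
        const double *ki = &K[(size_t)i * n];
        for (int j = 0; j < n; ++j) g[j] += delta * ki[j];
        if (std::fabs(delta) > max_delta) max_delta = std::fabs(delta);
      }
    }
    if (max_delta < tol) { ++sweeps; break; }
  }
  return List::create(_["beta"] = wrap(beta), _["sweeps"] = sweeps);
}

// [[Rcpp::export(name = ".svr_predict")]]
NumericVector svr_predict(NumericMatrix Xtrain, NumericVector beta,
                          double gamma, NumericMatrix Xnew) {
  int n = Xtrain.nrow(), p = Xtrain.ncol(), m = Xnew.nrow();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (beta[i] == 0.0) continue;
      double d2 = 0.0;
      for (int f = 0; f < p; ++f)
        d2 += sq(Xtrain[(size_t)f * n + i] - Xnew[(size_t)f * m + k]);
      s += beta[i] * (std::exp(-gamma * d2) + 1.0);
    }
    out[k] = s;
  }
  return out;
}
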
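#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Coordinate-descent LASSO for sparse coding against a dictionary.
//
// Solves, for every column y of Y,
//   min_alpha ||y - X alpha||_2^2 + lambda ||alpha||_1
// by cyclic coordinate descent on the unscaled objective (note: no 1/2n
// factor, so the soft threshold is lambda/2). lambda = 0 degenerates to
// least squares on the dictionary atoms.
//
// Convergence follows the glmnet criterion: a sweep converges when the
// largest single-coordinate objective move max_j ||x_j||^2 delta_j^2 drops
// below tol * max(||y||^2, 1). A plain coefficient-change criterion stalls
// on near-collinear dictionaries (the objective is flat along the shared
// direction while coefficients keep crawling).
//
// X: d x m dictionary (atoms as columns); Y: d x k targets.
// Returns alpha (m x k), per-target iteration counts and convergence flags.
// [[Rcpp::export(name = ".lasso_cd_cpp")]]
List lasso_cd_cpp(NumericMatrix X, NumericMatrix Y, double lambda,
                  double tol, int maxit) {
  const int d = X.nrow(), m = X.ncol(), k = Y.ncol();
  NumericMatrix alpha(m, k);
  IntegerVector iters(k);
  LogicalVector converged(k);
  std::vector<double> xnorm(m);
  for (int j = 0; j < m; ++j) {
    double s = 0;
    for (int i = 0; i < d; ++i) s += X(i, j) * X(i, j);
    xnorm[j] = s;
  }
  const double thr = lambda / 2.0;
  std::vector<double> r(d);
  for (int t = 0; t < k; ++t) {
    double ynorm = 0;
    for (int i = 0; i < d; ++i) { r[i] = Y(i, t); ynorm += r[i] * r[i]; }
    const double scale = std::max(ynorm, 1.0);
    int it = 0;
    bool ok = false;
    for (; it < maxit; ++it) {
      double maxmove = 0;
      for (int j = 0; j < m; ++j) {
        if (xnorm[j] <= 0) continue;
        double old = alpha(j, t);
        double rho = 0;
        for (int i = 0; i < d; ++i) rho += X(i, j) * r[i];
        rho += xnorm[j] * old;
        double next = soft(rho, thr) / xnorm[j];
        if (next != old) {
          double del = old - next;
          for (int i = 0; i < d; ++i) r[i] += X(i, j) * del;
          alpha(j, t) = next;
          maxmove = std::max(maxmove, xnorm[j] * del * del);
        }
      }
      if (maxmove < tol * scale) { ok = true; ++it; break; }
    }
    iters[t] = it;
    converged[t] = ok;
  }
  return List::create(_["alpha"] = alpha, _["iters"] = iters,
                      _["converged"] = converged);
}
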
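#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for L1-penalised least squares with a
// per-predictor penalty vector:
//   (1/2N) * sum_i (y_i - sum_j w_j x_ij)^2 + lambda * sum_j v_j |w_j|
// Residuals are updated in place; each coordinate step is the exact
// one-dimensional minimiser, so the objective is non-increasing.
// Columns need not have x_j'x_j == N: the update divides by d_j = x_j'x_j/N.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cd_lasso_cpp(const NumericMatrix& X, const NumericVector& y,
                  double lambda, const NumericVector& v,
                  NumericVector w_init, double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector w = clone(w_init);
  std::vector<double> r(n), d(p);

  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    double ss = 0.0;
    for (int i = 0; i < n; ++i) ss += X(i, j) * X(i, j);
    d[j] = ss / n;
    if (w[j] != 0.0) for (int i = 0; i < n; ++i) r[i] -= X(i, j) * w[j];
  }

  bool converged = false;
  int sweep = 0;
  for (; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (d[j] <= 0.0) { w[j] = 0.0; continue; } // constant (all-zero) column
      double xr = 0.0;
      for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
      const double cj = xr / n + d[j] * w[j];   // (1/N) x_j' r_{-j}
      const double wj_new = soft(cj, lambda * v[j]) / d[j];
      const double delta = wj_new - w[j];
      if (delta != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * delta;
        w[j] = wj_new;
        double ad = std::fabs(delta);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) { converged = true; ++sweep; break; }
  }

  double rss = 0.0;
  for (int i = 0; i < n; ++i) rss += r[i] * r[i];
  double pen = 0.0;
  for (int j = 0; j < p; ++j) pen += v[j] * std::fabs(w[j]);

  return List::create(_["w"] = w,
                      _["n_sweeps"] = sweep,
                      _["converged"] = converged,
                      _["final_cost"] = rss / (2.0 * n) + lambda * pen);
}

// Warm-started solution path over a decreasing lambda grid.
// Returns a p x n_lambda coefficient matrix.
// [[Rcpp::export]]
NumericMatrix cd_lasso_path_cpp(const NumericMatrix& X, const NumericVector& y,
                                const NumericVector& lambdas,
                                const NumericVector& v,
                                double tol, int max_sweeps) {
  const int p = X.ncol(), nl = lambdas.size();
  NumericMatrix W(p, nl);
  NumericVector w(p);
  for (int l = 0; l < nl; ++l) {
    List fit = cd_lasso_cpp(X, y, lambdas[l], v, w, tol, max_sweeps);
    w = fit["w"];
    for (int j = 0; j < p; ++j) W(j, l) = w[j];
  }
  return W;
}
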
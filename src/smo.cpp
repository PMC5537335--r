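#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual
//   min 1/2 a'Qa - e'a,  0 <= a_i <= C,  y'a = 0,  Q_ij = y_i y_j K_ij
// on a precomputed kernel (Gram) matrix. Maximal-violating-pair working-set
// selection; returns alpha and the intercept b of f(x) = sum a_i y_i K(x,i) + b.
// A kernel-level interface lets callers reuse one Gram matrix across the
// thousands of refits a permutation test performs.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double eps = 1e-8, int max_iter = 200000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  double b = 0.0;
  for (; iter < max_iter; ++iter) {
    // i maximizes -y_t G_t over I_up, j minimizes it over I_low
    int i = -1, j = -1;
    double vmax = -HUGE_VAL, vmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > vmax)  { vmax = v; i = t; }
      if (low && v < vmin) { vmin = v; j = t; }
    }
    if (i < 0 || j < 0 || vmax - vmin < eps) break;

    // curvature along the feasible direction (d_i = y_i, d_j = -y_j):
    // d'Qd = K_ii + K_jj - 2 K_ij for any label combination
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;
    double lambda = (vmax - vmin) / quad;

    // box constraints for alpha_i += y_i*lambda, alpha_j -= y_j*lambda
    lambda = std::min(lambda, (y[i] > 0) ? (C - alpha[i]) : alpha[i]);
    lambda = std::min(lambda, (y[j] > 0) ? alpha[j] : (C - alpha[j]));
    if (lambda <= 0) break;

    alpha[i] += y[i] * lambda;
    alpha[j] -= y[j] * lambda;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * lambda * (K(t, i) - K(t, j));
  }

  // intercept: average of -y_t G_t over free support vectors, else midpoint
  // of the feasibility interval
  int nfree = 0;
  double bsum = 0.0, vmax = -HUGE_VAL, vmin = HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    const double v = -y[t] * G[t];
    const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
    const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { bsum += v; ++nfree; }
    if (up && v > vmax) vmax = v;
    if (low && v < vmin) vmin = v;
  }
  b = (nfree > 0) ? bsum / nfree : (vmax + vmin) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
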
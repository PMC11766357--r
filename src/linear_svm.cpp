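#include <Rcpp.h>
using namespace Rcpp;

// Deterministic dual coordinate-descent solver for the L1-loss linear SVM
//   min_{w,b} 0.5 * (||w||^2 + b^2) + C * sum_i max(0, 1 - y_i (w.x_i + b))
// The bias is regularized via an augmented constant feature, which keeps the
// dual box-constrained (0 <= alpha_i <= C) with no equality constraint.
// Sweeps run in fixed sample order from a zero start until the maximum
// projected-gradient violation falls below `tol`, so the solution is fully
// deterministic.
// [[Rcpp::export]]
List svm_linear_dcd(NumericMatrix X, NumericVector y, double C,
                    double tol = 1e-8, int max_sweeps = 100000) {
  const int n = X.nrow();
  const int d = X.ncol();
  std::vector<double> w(d + 1, 0.0); // last component is the bias
  std::vector<double> alpha(n, 0.0);
  std::vector<double> Qii(n);
  for (int i = 0; i < n; ++i) {
    double q = 1.0; // augmented constant feature
    for (int j = 0; j < d; ++j) q += X(i, j) * X(i, j);
    Qii[i] = q;
  }
  int sweep = 0;
  bool converged = false;
  double last_viol = 0.0;
  for (; sweep < max_sweeps; ++sweep) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      double dec = w[d]; // bias term times augmented 1
      for (int j = 0; j < d; ++j) dec += w[j] * X(i, j);
      double G = y[i] * dec - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-15) {
        double a_new = alpha[i] - G / Qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        double delta = a_new - alpha[i];
        if (delta != 0.0) {
          alpha[i] = a_new;
          for (int j = 0; j < d; ++j) w[j] += delta * y[i] * X(i, j);
          w[d] += delta * y[i];
        }
      }
    }
    last_viol = max_viol;
    if (max_viol < tol) { converged = true; break; }
  }
  NumericVector weights(d);
  for (int j = 0; j < d; ++j) weights[j] = w[j];
  return List::create(_["weights"] = weights, _["bias"] = w[d],
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["sweeps"] = sweep, _["converged"] = converged,
                      _["final_violation"] = last_viol);
}
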
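#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin C-SVC dual on a
// precomputed kernel matrix:
//
//   min_a  0.5 * a' Q a - e' a,   Q_ij = y_i y_j K_ij
//   s.t.   0 <= a_i <= C,  sum_i y_i a_i = 0
//
// Working-set selection is the maximal violating pair; convergence is the
// standard KKT gap m(a) - M(a) < eps. Operating on K (not on features)
// lets callers update the Gram matrix by rank-1 downdates when a feature
// is dropped, which is what makes exhaustive backward elimination cheap.
//
// A feasible starting point (e.g. the solution for a one-feature-larger
// panel during backward elimination) can be supplied through alpha0;
// the gradient is then rebuilt from it, which typically cuts the
// iteration count by an order of magnitude.
//
// Returns alpha, rho (decision value f(x) = sum_j a_j y_j K(x_j, x) - rho),
// the per-training-sample decision values, and the iteration count.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, double cost,
               double eps = 1e-3, int max_iter = 1000000,
               Nullable<NumericVector> alpha0 = R_NilValue) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length must match kernel dimension");

  const double* Kp = K.begin();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  if (alpha0.isNotNull()) {
    NumericVector a0(alpha0);
    if (a0.size() != n) stop("alpha0 length must match kernel dimension");
    for (int i = 0; i < n; ++i) alpha[i] = a0[i];
    for (int j = 0; j < n; ++j) {
      if (alpha[j] == 0.0) continue;
      const double ayj = alpha[j] * y[j];
      const double* Kj = Kp + (size_t)j * n;
      for (int t = 0; t < n; ++t) G[t] += y[t] * Kj[t] * ayj;
    }
  }

  const double C = cost;
  int iter = 0;
  double m_up = 0.0, M_low = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair over I_up / I_low
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    M_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up && v > m_up)  { m_up = v;  i = t; }
      if (in_low && v < M_low) { M_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - M_low < eps) break;

    // step along a_i += y_i * t, a_j -= y_j * t (keeps the equality
    // constraint); unconstrained optimum t* = (m_up - M_low) / eta
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;
    double step = (m_up - M_low) / eta;

    double bound_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double bound_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (step > bound_i) step = bound_i;
    if (step > bound_j) step = bound_j;

    alpha[i] += y[i] > 0 ? step : -step;
    alpha[j] -= y[j] > 0 ? step : -step;
    // G_k += y_k * step * (K_ki - K_kj)
    const double* Ki = Kp + (size_t)i * n;
    const double* Kj = Kp + (size_t)j * n;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * step * (Ki[t] - Kj[t]);
  }

  // rho from free support vectors, midpoint of the KKT bounds otherwise
  double rho;
  {
    double sum = 0.0; int nfree = 0;
    for (int t = 0; t < n; ++t)
      if (alpha[t] > 0 && alpha[t] < C) { sum += y[t] * G[t]; ++nfree; }
    rho = nfree > 0 ? sum / nfree : -(m_up + M_low) / 2.0;
  }

  // decision values for the training points: f_i = y_i G_i + y_i - rho
  NumericVector dec(n);
  for (int t = 0; t < n; ++t) dec[t] = y[t] * G[t] + y[t] - rho;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho,
                      _["decision"] = dec,
                      _["iterations"] = iter);
}
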
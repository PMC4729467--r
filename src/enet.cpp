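#include <Rcpp.h>
using namespace Rcpp;

// Elastic-net objective:
//   (1/2n) * sum_i (y_i - b - x_i.w)^2
//     + lambda * ( alpha * sum_j |w_j| + (1-alpha)/2 * sum_j w_j^2 )
// minimised by cyclic coordinate descent with soft-thresholding and an
// active-set strategy (iterate the nonzero set to convergence, then one full
// sweep to check the optimality of the zeros).

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double objective(const std::vector<double>& r, int n,
                        const std::vector<double>& w, double lambda,
                        double alpha) {
  double rss = 0.0;
  for (int i = 0; i < n; ++i) rss += r[i] * r[i];
  double l1 = 0.0, l2 = 0.0;
  for (size_t j = 0; j < w.size(); ++j) {
    l1 += std::fabs(w[j]);
    l2 += w[j] * w[j];
  }
  return rss / (2.0 * n) + lambda * (alpha * l1 + 0.5 * (1.0 - alpha) * l2);
}

// One pass over the coordinate set `idx`; returns max |coefficient change|.
static double sweep_set(const NumericMatrix& X, std::vector<double>& r,
                        std::vector<double>& w, double& b, int n,
                        const std::vector<int>& idx, const std::vector<double>& msq,
                        double lambda, double alpha, bool fit_intercept) {
  double maxd = 0.0;
  for (int jj : idx) {
    double rho = 0.0;
    const double* xj = &X(0, jj);
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    rho = rho / n + msq[jj] * w[jj];
    double denom = msq[jj] + lambda * (1.0 - alpha);
    double wn = denom > 0 ? soft(rho, lambda * alpha) / denom : 0.0;
    double d = wn - w[jj];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
      w[jj] = wn;
      if (std::fabs(d) > maxd) maxd = std::fabs(d);
    }
  }
  if (fit_intercept) {
    double rbar = 0.0;
    for (int i = 0; i < n; ++i) rbar += r[i];
    rbar /= n;
    if (rbar != 0.0) {
      b += rbar;
      for (int i = 0; i < n; ++i) r[i] -= rbar;
      if (std::fabs(rbar) > maxd) maxd = std::fabs(rbar);
    }
  }
  return maxd;
}

// [[Rcpp::export]]
List enet_cd(NumericMatrix X, NumericVector y, double lambda, double alpha,
             int max_iter, double tol, NumericVector w0, double b0,
             bool fit_intercept, bool trace) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> w(w0.begin(), w0.end());
  double b = b0;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double fit = b;
    for (int j = 0; j < p; ++j)
      if (w[j] != 0.0) fit += X(i, j) * w[j];
    r[i] = y[i] - fit;
  }
  std::vector<double> msq(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    msq[j] = s / n;
  }
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;

  std::vector<double> obj;
  if (trace) obj.push_back(objective(r, n, w, lambda, alpha));
  bool converged = false;
  int iter = 0;
  while (iter < max_iter) {
    double d = sweep_set(X, r, w, b, n, all, msq, lambda, alpha, fit_intercept);
    ++iter;
    if (trace) obj.push_back(objective(r, n, w, lambda, alpha));
    if (d < tol) { converged = true; break; }
    // active-set inner loop
    std::vector<int> act;
    for (int j = 0; j < p; ++j)
      if (w[j] != 0.0) act.push_back(j);
    while (iter < max_iter && !act.empty()) {
      double da = sweep_set(X, r, w, b, n, act, msq, lambda, alpha, fit_intercept);
      ++iter;
      if (trace) obj.push_back(objective(r, n, w, lambda, alpha));
      if (da < tol) break;
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b,
                      _["objective"] = NumericVector(obj.begin(), obj.end()),
                      _["converged"] = converged,
                      _["iterations"] = iter);
}

// Warm-started solution path over a decreasing lambda sequence.
// [[Rcpp::export]]
List enet_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
               double alpha, int max_iter, double tol, bool fit_intercept) {
  const int p = X.ncol(), nl = lambdas.size();
  NumericMatrix W(p, nl);
  NumericVector B(nl);
  NumericVector w(p);
  double b = 0.0;
  for (int k = 0; k < nl; ++k) {
    List fit = enet_cd(X, y, lambdas[k], alpha, max_iter, tol, w, b,
                       fit_intercept, false);
    NumericVector wk = fit["w"];
    b = as<double>(fit["b"]);
    for (int j = 0; j < p; ++j) {
      w[j] = wk[j];
      W(j, k) = wk[j];
    }
    B[k] = b;
  }
  return List::create(_["W"] = W, _["b"] = B);
}
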
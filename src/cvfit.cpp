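#include <Rcpp.h>
using namespace Rcpp;

List enet_cd(NumericMatrix X, NumericVector y, double lambda, double alpha,
             int max_iter, double tol, NumericVector w0, double b0,
             bool fit_intercept, bool trace);
List enet_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
               double alpha, int max_iter, double tol, bool fit_intercept);

static void col_stats(const NumericMatrix& X, std::vector<double>& mu,
                      std::vector<double>& sd) {
  const int n = X.nrow(), p = X.ncol();
  mu.assign(p, 0.0);
  sd.assign(p, 1.0);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j);
    mu[j] = s / n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = X(i, j) - mu[j];
      v += d * d;
    }
    v = n > 1 ? v / (n - 1) : 0.0;
    sd[j] = v > 0 ? std::sqrt(v) : 1.0;
  }
}

static NumericMatrix standardize(const NumericMatrix& X,
                                 const std::vector<double>& mu,
                                 const std::vector<double>& sd) {
  NumericMatrix out(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      out(i, j) = (X(i, j) - mu[j]) / sd[j];
  return out;
}

// One bagged-ensemble member: choose lambda on (Xtr, ytr) by inner k-fold CV
// over `grid` (fold labels supplied by the caller, whose RNG owns them),
// refit on the whole training set at the chosen lambda, and predict Xte.
// Standardization statistics always come from the training side of each
// split. Returns the test predictions and the weights on the standardized
// scale.
// [[Rcpp::export]]
List cv_fit_predict(NumericMatrix Xtr, NumericVector ytr, NumericMatrix Xte,
                    IntegerVector inner_fold, NumericVector grid, double alpha,
                    int path_iter, double path_tol, int final_iter,
                    double final_tol, bool do_standardize) {
  const int n = Xtr.nrow(), p = Xtr.ncol(), nl = grid.size();
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, inner_fold[i]);
  std::vector<double> mse(nl, 0.0);
  for (int f = 1; f <= k; ++f) {
    std::vector<int> tr, te;
    for (int i = 0; i < n; ++i) (inner_fold[i] == f ? te : tr).push_back(i);
    if (te.empty() || tr.size() < 2) continue;
    NumericMatrix Xa((int)tr.size(), p), Xb((int)te.size(), p);
    NumericVector ya((int)tr.size());
    for (size_t i = 0; i < tr.size(); ++i) {
      for (int j = 0; j < p; ++j) Xa(i, j) = Xtr(tr[i], j);
      ya[i] = ytr[tr[i]];
    }
    for (size_t i = 0; i < te.size(); ++i)
      for (int j = 0; j < p; ++j) Xb(i, j) = Xtr(te[i], j);
    if (do_standardize) {
      std::vector<double> mu, sd;
      col_stats(Xa, mu, sd);
      Xa = standardize(Xa, mu, sd);
      Xb = standardize(Xb, mu, sd);
    }
    List path = enet_path(Xa, ya, grid, alpha, path_iter, path_tol, true);
    NumericMatrix W = path["W"];
    NumericVector b = path["b"];
    for (int l = 0; l < nl; ++l) {
      double err = 0.0;
      for (size_t i = 0; i < te.size(); ++i) {
        double pred = b[l];
        for (int j = 0; j < p; ++j) pred += Xb(i, j) * W(j, l);
        double d = pred - ytr[te[i]];
        err += d * d;
      }
      mse[l] += err;
    }
  }
  int best = 0;
  for (int l = 1; l < nl; ++l)
    if (mse[l] < mse[best]) best = l;

  NumericMatrix Xs = Xtr, Xp = Xte;
  if (do_standardize) {
    std::vector<double> mu, sd;
    col_stats(Xtr, mu, sd);
    Xs = standardize(Xtr, mu, sd);
    if (Xte.nrow() > 0) Xp = standardize(Xte, mu, sd);
  }
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += ytr[i];
  ybar /= n;
  List fit = enet_cd(Xs, ytr, grid[best], alpha, final_iter, final_tol,
                     NumericVector(p), ybar, true, false);
  NumericVector w = fit["w"];
  double b0 = as<double>(fit["b"]);
  NumericVector pred(Xte.nrow());
  for (int i = 0; i < Xte.nrow(); ++i) {
    double s = b0;
    for (int j = 0; j < p; ++j) s += Xp(i, j) * w[j];
    pred[i] = s;
  }
  return List::create(_["pred"] = pred, _["w"] = w,
                      _["lambda"] = grid[best]);
}
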
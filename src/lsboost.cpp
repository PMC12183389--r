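#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Depth-1 regression stump on a single predictor: pick the split (midpoint
// between adjacent sorted x) minimising residual SSE; leaf values are the
// residual means on each side. ord = indices of x in ascending order.
static void fit_stump(const std::vector<double>& x,
                      const std::vector<int>& ord,
                      const std::vector<double>& r,
                      const std::vector<double>& inv, // inv[i] = 1.0 / i
                      double& split, double& left, double& right) {
  const int n = (int)x.size();
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += r[i];
  const double base_score = tot * tot * inv[n];
  double best_gain = -1.0;
  int best_k = -1, best_nl = 0;
  double best_cum = 0.0, cum = 0.0;
  for (int k = 0; k < n - 1; ++k) {
    cum += r[ord[k]];
    if (x[ord[k]] == x[ord[k + 1]]) continue; // cannot split between ties
    const int nl = k + 1;
    const double rest = tot - cum;
    // SSE reduction relative to a single leaf
    const double gain = cum * cum * inv[nl] + rest * rest * inv[n - nl] - base_score;
    if (gain > best_gain + 1e-15) {
      best_gain = gain;
      best_k = k;
      best_nl = nl;
      best_cum = cum;
    }
  }
  if (best_k < 0) { // constant x: single leaf
    split = R_PosInf;
    left = right = tot * inv[n];
    return;
  }
  split = 0.5 * (x[ord[best_k]] + x[ord[best_k + 1]]);
  left = best_cum * inv[best_nl];
  right = (tot - best_cum) * inv[n - best_nl];
}

// [[Rcpp::export]]
List lsboost_fit_cpp(NumericVector x, NumericVector y,
                     int n_learners, double learning_rate) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xv[a] < xv[b]; });

  std::vector<double> inv(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) inv[i] = 1.0 / i;

  double base = 0.0;
  for (int i = 0; i < n; ++i) base += yv[i];
  base /= n;

  std::vector<double> f(n, base), r(n);
  NumericMatrix stumps(n_learners, 3); // split, left, right
  NumericVector train_rmse(n_learners);
  for (int m = 0; m < n_learners; ++m) {
    for (int i = 0; i < n; ++i) r[i] = yv[i] - f[i];
    double split, left, right;
    fit_stump(xv, ord, r, inv, split, left, right);
    stumps(m, 0) = split;
    stumps(m, 1) = left;
    stumps(m, 2) = right;
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      f[i] += learning_rate * (xv[i] <= split ? left : right);
      const double e = yv[i] - f[i];
      sse += e * e;
    }
    train_rmse[m] = std::sqrt(sse / n);
  }
  return List::create(_["base"] = base, _["stumps"] = stumps,
                      _["train_rmse"] = train_rmse);
}

// [[Rcpp::export]]
NumericVector lsboost_predict_cpp(double base, NumericMatrix stumps,
                                  double learning_rate, NumericVector x) {
  const int n = x.size(), m = stumps.nrow();
  NumericVector out(n, base);
  for (int j = 0; j < m; ++j) {
    const double s = stumps(j, 0), l = stumps(j, 1), r = stumps(j, 2);
    for (int i = 0; i < n; ++i) out[i] += learning_rate * (x[i] <= s ? l : r);
  }
  return out;
}

// Per-biomarker held-out RMSE for one train/test split: column j of X is one
// biomarker's intensities; fit x_j -> y on the training rows and score on
// the test rows.
// [[Rcpp::export]]
NumericVector lsboost_split_rmse_cpp(NumericMatrix X, NumericVector y,
                                     IntegerVector train_idx,
                                     IntegerVector test_idx,
                                     int n_learners, double learning_rate) {
  const int p = X.ncol();
  const int ntr = train_idx.size(), nte = test_idx.size();
  NumericVector out(p);
  std::vector<double> xtr(ntr), ytr(ntr), xte(nte), yte(nte);
  for (int i = 0; i < ntr; ++i) ytr[i] = y[train_idx[i] - 1];
  for (int i = 0; i < nte; ++i) yte[i] = y[test_idx[i] - 1];
  std::vector<int> ord(ntr);
  std::vector<double> f(ntr), r(ntr);
  std::vector<double> inv(ntr + 1, 0.0);
  for (int i = 1; i <= ntr; ++i) inv[i] = 1.0 / i;

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < ntr; ++i) xtr[i] = X(train_idx[i] - 1, j);
    for (int i = 0; i < nte; ++i) xte[i] = X(test_idx[i] - 1, j);
    for (int i = 0; i < ntr; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xtr[a] < xtr[b]; });
    double base = 0.0;
    for (int i = 0; i < ntr; ++i) base += ytr[i];
    base /= ntr;
    std::fill(f.begin(), f.end(), base);
    std::vector<double> fte(nte, base);
    for (int m = 0; m < n_learners; ++m) {
      for (int i = 0; i < ntr; ++i) r[i] = ytr[i] - f[i];
      double split, left, right;
      fit_stump(xtr, ord, r, inv, split, left, right);
      for (int i = 0; i < ntr; ++i)
        f[i] += learning_rate * (xtr[i] <= split ? left : right);
      for (int i = 0; i < nte; ++i)
        fte[i] += learning_rate * (xte[i] <= split ? left : right);
    }
    double sse = 0.0;
    for (int i = 0; i < nte; ++i) {
      const double e = yte[i] - fte[i];
      sse += e * e;
    }
    out[j] = std::sqrt(sse / nte);
  }
  return out;
}
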
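#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for L2-regularized L1-loss linear SVM:
//   min_w  0.5 * w'w + C * sum_i max(0, 1 - y_i w'x_i)
// Bias is handled by the caller through feature augmentation (constant
// column). The sweep order is the fixed sequence 1..n on every pass, so
// the fit is fully deterministic: no RNG is consumed.
//
// X is dense (n x p); fingerprints are short binary rows, so n and p are
// small (hundreds) and the dense product is cheaper than sparse overhead.
// [[Rcpp::export(name = ".svm_dcd_fit")]]
NumericVector svm_dcd_fit(NumericMatrix X, NumericVector y, double C,
                          int max_passes = 300, double tol = 1e-4) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector w(p);
  std::vector<double> alpha(n, 0.0), qii(n);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }

  for (int pass = 0; pass < max_passes; ++pass) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      if (qii[i] <= 0.0) continue;  // all-zero row: alpha stays 0
      double wx = 0.0;
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;

      double PG = G;  // projected gradient respecting the box [0, C]
      if (alpha[i] <= 0.0)      PG = std::min(G, 0.0);
      else if (alpha[i] >= C)   PG = std::max(G, 0.0);
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);

      if (std::fabs(PG) > 1e-14) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / qii[i], 0.0), C);
        alpha[i] = a_new;
        double d = (a_new - a_old) * y[i];
        if (d != 0.0) for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
      }
    }
    if (max_pg < tol) break;
  }
  return w;
}

// Cost-path variant for cross-validated cost selection: fits the same
// training data over an ascending cost grid, warm-starting alpha from
// the previous cost (the solution path is continuous in C), and returns
// the decision values of the held-out rows for every cost.
// [[Rcpp::export(name = ".svm_dcd_path")]]
NumericMatrix svm_dcd_path(NumericMatrix X, NumericVector y,
                           NumericMatrix Xtest, NumericVector costs,
                           int max_passes = 300, double tol = 1e-4) {
  const int n = X.nrow(), p = X.ncol(), m = Xtest.nrow(), nc = costs.size();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);
  NumericMatrix dec(m, nc);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }

  for (int c = 0; c < nc; ++c) {
    const double C = costs[c];
    for (int i = 0; i < n; ++i) if (alpha[i] > C) {
      // shrink into the new box, keeping w consistent
      double d = (C - alpha[i]) * y[i];
      alpha[i] = C;
      for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
    }
    for (int pass = 0; pass < max_passes; ++pass) {
      double max_pg = 0.0;
      for (int i = 0; i < n; ++i) {
        if (qii[i] <= 0.0) continue;
        double wx = 0.0;
        for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
        double G = y[i] * wx - 1.0;
        double PG = G;
        if (alpha[i] <= 0.0)    PG = std::min(G, 0.0);
        else if (alpha[i] >= C) PG = std::max(G, 0.0);
        if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
        if (std::fabs(PG) > 1e-14) {
          double a_old = alpha[i];
          double a_new = std::min(std::max(a_old - G / qii[i], 0.0), C);
          alpha[i] = a_new;
          double d = (a_new - a_old) * y[i];
          if (d != 0.0) for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        }
      }
      if (max_pg < tol) break;
    }
    for (int t = 0; t < m; ++t) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += w[j] * Xtest(t, j);
      dec(t, c) = s;
    }
  }
  return dec;
}
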
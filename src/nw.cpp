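#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nadaraya-Watson estimates with a product Gaussian kernel.
// Q: queries (q x d), X: sample locations (n x d), y: responses (n),
// h: bandwidth per dimension (d). Returns the weighted average and the
// total kernel weight mass per query (normalized kernel, so the mass of a
// single coincident sample is (2*pi)^(-d/2)).
// [[Rcpp::export]]
List nw_cpp(NumericMatrix Q, NumericMatrix X, NumericVector y,
            NumericVector h) {
  const int q = Q.nrow(), n = X.nrow(), d = Q.ncol();
  if (X.ncol() != d || h.size() != d)
    stop("dimension mismatch between queries, samples and bandwidths");
  if (y.size() != n) stop("y must have one value per sample");
  std::vector<double> inv(d);
  double norm = 1.0;
  for (int k = 0; k < d; ++k) {
    inv[k] = 1.0 / h[k];
    norm /= std::sqrt(2.0 * M_PI);
  }
  NumericVector est(q), mass(q);
  for (int i = 0; i < q; ++i) {
    double sw = 0.0, swy = 0.0;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double u = (Q(i, k) - X(j, k)) * inv[k];
        s += u * u;
      }
      double w = norm * std::exp(-0.5 * s);
      sw += w;
      swy += w * y[j];
    }
    mass[i] = sw;
    est[i] = sw > 0.0 ? swy / sw : NA_REAL;
  }
  return List::create(_["estimate"] = est, _["mass"] = mass);
}

// Leave-one-out NW predictions at the sample locations themselves
// (used by cross-validation bandwidth selection).
// [[Rcpp::export]]
NumericVector nw_loo_cpp(NumericMatrix X, NumericVector y, NumericVector h) {
  const int n = X.nrow(), d = X.ncol();
  if (h.size() != d) stop("bandwidth length must match the sample dimension");
  std::vector<double> inv(d);
  double norm = 1.0;
  for (int k = 0; k < d; ++k) {
    inv[k] = 1.0 / h[k];
    norm /= std::sqrt(2.0 * M_PI);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double sw = 0.0, swy = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double u = (X(i, k) - X(j, k)) * inv[k];
        s += u * u;
      }
      double w = norm * std::exp(-0.5 * s);
      sw += w;
      swy += w * y[j];
    }
    out[i] = sw > 0.0 ? swy / sw : NA_REAL;
  }
  return out;
}
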
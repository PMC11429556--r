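#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the two-class C-SVC dual with a
// precomputed kernel matrix. Working-set selection is the maximal violating
// pair; stopping rule m(alpha) - M(alpha) <= eps as in standard SMO solvers.
// The kernel is passed in full and solves operate on an index subset, so
// leave-one-out folds and label permutations all reuse one Gram matrix.

namespace {

struct SvcFit {
  std::vector<double> alpha; // per active sample
  double b;                  // intercept: decision f(x) = sum a_i y_i K(x_i,x) + b
  bool one_class;            // training set had a single class
  int one_class_label;       // +1/-1 when one_class
};

// K: full n x n kernel, y: full +1/-1 labels, idx: active sample indices
SvcFit smo_solve(const NumericMatrix& K, const int* y, const std::vector<int>& idx,
                 double C, double eps, int max_iter) {
  const int m = (int)idx.size();
  SvcFit fit;
  fit.alpha.assign(m, 0.0);
  fit.b = 0.0;
  fit.one_class = false;
  fit.one_class_label = 0;

  int pos = 0;
  for (int t = 0; t < m; ++t) if (y[idx[t]] > 0) ++pos;
  if (pos == 0 || pos == m) {
    fit.one_class = true;
    fit.one_class_label = (pos == m) ? 1 : -1;
    return fit;
  }

  // f_t = sum_j alpha_j y_j K(j, t); alpha starts at 0 so f = 0
  std::vector<double> f(m, 0.0);
  std::vector<double> a(m, 0.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair on -y * grad = y - f
    double up = -HUGE_VAL, lo = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < m; ++t) {
      const int yt = y[idx[t]];
      const double v = yt - f[t];
      const bool in_up = (yt > 0) ? (a[t] < C) : (a[t] > 0);
      const bool in_lo = (yt > 0) ? (a[t] > 0) : (a[t] < C);
      if (in_up && v > up) { up = v; i = t; }
      if (in_lo && v < lo) { lo = v; j = t; }
    }
    if (i < 0 || j < 0 || up - lo <= eps) break;

    const int gi = idx[i], gj = idx[j];
    const int yi = y[gi], yj = y[gj];
    const double kii = K(gi, gi), kjj = K(gj, gj), kij = K(gi, gj);
    double eta = kii + kjj - 2.0 * kij;
    if (eta <= 1e-12) eta = 1e-12;

    const double Ei = f[i] - yi, Ej = f[j] - yj;
    double aj_new = a[j] + yj * (Ei - Ej) / eta;

    double L, H;
    if (yi != yj) { L = std::max(0.0, a[j] - a[i]); H = std::min(C, C + a[j] - a[i]); }
    else          { L = std::max(0.0, a[i] + a[j] - C); H = std::min(C, a[i] + a[j]); }
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;

    const double dj = aj_new - a[j];
    if (std::fabs(dj) < 1e-14) break; // stalled at bounds
    const double s = (double)(yi * yj);
    double ai_new = a[i] - s * dj;
    // snap to exact bounds so working-set membership stays consistent
    const double snap = 1e-12 * C;
    if (ai_new < snap) ai_new = 0.0;
    if (ai_new > C - snap) ai_new = C;
    if (aj_new < snap) aj_new = 0.0;
    if (aj_new > C - snap) aj_new = C;
    const double di = ai_new - a[i];
    a[i] = ai_new;
    a[j] = aj_new;
    for (int t = 0; t < m; ++t)
      f[t] += di * yi * K(gi, idx[t]) + dj * yj * K(gj, idx[t]);
  }

  // intercept from free support vectors, else midpoint of the violating gap
  double bsum = 0.0; int nfree = 0;
  const double tol = 1e-8;
  for (int t = 0; t < m; ++t)
    if (a[t] > tol && a[t] < C - tol) { bsum += y[idx[t]] - f[t]; ++nfree; }
  if (nfree > 0) {
    fit.b = bsum / nfree;
  } else {
    double up = -HUGE_VAL, lo = HUGE_VAL;
    for (int t = 0; t < m; ++t) {
      const int yt = y[idx[t]];
      const double v = yt - f[t];
      const bool in_up = (yt > 0) ? (a[t] < C) : (a[t] > 0);
      const bool in_lo = (yt > 0) ? (a[t] > 0) : (a[t] < C);
      if (in_up && v > up) up = v;
      if (in_lo && v < lo) lo = v;
    }
    fit.b = (up == -HUGE_VAL || lo == HUGE_VAL) ? 0.0 : (up + lo) / 2.0;
  }
  fit.alpha = a;
  return fit;
}

// decision value for full-matrix column q given a fit on idx
double decide(const NumericMatrix& K, const int* y, const std::vector<int>& idx,
              const SvcFit& fit, int q) {
  if (fit.one_class) return (double)fit.one_class_label;
  double f = fit.b;
  for (size_t t = 0; t < idx.size(); ++t)
    if (fit.alpha[t] != 0.0) f += fit.alpha[t] * y[idx[t]] * K(idx[t], q);
  return f;
}

} // namespace

// [[Rcpp::export(name = ".svc_fit_kernel")]]
List svc_fit_kernel(NumericMatrix K, IntegerVector y, double C,
                    double eps = 1e-3, int max_iter = 1000000) {
  const int n = K.nrow();
  if (y.size() != n) stop("label length does not match kernel size");
  std::vector<int> idx(n);
  for (int t = 0; t < n; ++t) idx[t] = t;
  SvcFit fit = smo_solve(K, y.begin(), idx, C, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b,
                      _["one_class"] = fit.one_class);
}

// Leave-one-out decision values: entry i is the decision value for sample i
// from an SVC trained on all other samples.
// [[Rcpp::export(name = ".svc_loo_decision")]]
NumericVector svc_loo_decision(NumericMatrix K, IntegerVector y, double C,
                               double eps = 1e-3, int max_iter = 1000000) {
  const int n = K.nrow();
  if (y.size() != n) stop("label length does not match kernel size");
  NumericVector out(n);
  std::vector<int> idx(n - 1);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int t = 0; t < n; ++t) if (t != i) idx[k++] = t;
    SvcFit fit = smo_solve(K, y.begin(), idx, C, eps, max_iter);
    out[i] = decide(K, y.begin(), idx, fit, i);
  }
  return out;
}

// LOO accuracy for each label column of Y (n x B), sharing one kernel.
// Ties (decision exactly 0) count as the tie_label class.
// [[Rcpp::export(name = ".svc_loo_accuracy_many")]]
NumericVector svc_loo_accuracy_many(NumericMatrix K, IntegerMatrix Y, double C,
                                    int tie_label, double eps = 1e-3,
                                    int max_iter = 1000000) {
  const int n = K.nrow(), B = Y.ncol();
  if (Y.nrow() != n) stop("label matrix rows do not match kernel size");
  NumericVector acc(B);
  std::vector<int> idx(n - 1);
  std::vector<int> yb(n);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < n; ++t) yb[t] = Y(t, b);
    int correct = 0;
    for (int i = 0; i < n; ++i) {
      int k = 0;
      for (int t = 0; t < n; ++t) if (t != i) idx[k++] = t;
      SvcFit fit = smo_solve(K, yb.data(), idx, C, eps, max_iter);
      const double f = decide(K, yb.data(), idx, fit, i);
      const int pred = (f > 0) ? 1 : (f < 0 ? -1 : tie_label);
      if (pred == yb[i]) ++correct;
    }
    acc[b] = (double)correct / n;
    if (b % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}
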
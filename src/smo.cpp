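#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Smo {
  const NumericMatrix& K;
  const NumericVector& y;
  double C, tol;
  int m;
  std::vector<double> a, E;
  double b;

  Smo(const NumericMatrix& K_, const NumericVector& y_, double C_, double tol_)
      : K(K_), y(y_), C(C_), tol(tol_), m(y_.size()), a(m, 0.0), E(m), b(0.0) {
    for (int i = 0; i < m; ++i) E[i] = -y[i];  // f = 0 initially
  }

  // attempt one analytic pair update; returns true if alphas moved
  bool take_step(int i, int j) {
    if (i == j) return false;
    const double ai_old = a[i], aj_old = a[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < 1e-12) return false;
    const double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) return false;  // flat direction (duplicate points)
    double aj_new = aj_old + y[j] * (E[i] - E[j]) / eta;
    if (aj_new > H) aj_new = H; else if (aj_new < L) aj_new = L;
    // snap to the box bounds to avoid alphas stranded epsilon-inside them;
    // the equality constraint stays exact because a_i is recomputed below
    const double eps = 1e-10 * (1.0 + C);
    if (aj_new - L < eps) aj_new = L; else if (H - aj_new < eps) aj_new = H;
    if (std::fabs(aj_new - aj_old) < 1e-12) return false;
    const double ai_new = ai_old + y[i] * y[j] * (aj_old - aj_new);
    a[i] = ai_new; a[j] = aj_new;
    const double di = y[i] * (ai_new - ai_old);
    const double dj = y[j] * (aj_new - aj_old);
    const double b1 = b - E[i] - di * K(i, i) - dj * K(i, j);
    const double b2 = b - E[j] - di * K(i, j) - dj * K(j, j);
    double b_new;
    if (ai_new > 0.0 && ai_new < C) b_new = b1;
    else if (aj_new > 0.0 && aj_new < C) b_new = b2;
    else b_new = 0.5 * (b1 + b2);
    const double db = b_new - b;
    b = b_new;
    for (int t = 0; t < m; ++t) E[t] += di * K(i, t) + dj * K(j, t) + db;
    return true;
  }

  bool violates(int i) const {
    const double ri = E[i] * y[i];
    const double eps = 1e-10 * (1.0 + C);  // at-bound slack for float roundoff
    return (ri < -tol && a[i] < C - eps) || (ri > tol && a[i] > eps);
  }

  // examine one violating index: best |E_i - E_j| partner first, then a
  // deterministic full scan
  bool examine(int i) {
    int jbest = -1; double best = -1.0;
    for (int t = 0; t < m; ++t) {
      if (t == i) continue;
      const double d = std::fabs(E[i] - E[t]);
      if (d > best) { best = d; jbest = t; }
    }
    if (jbest >= 0 && take_step(i, jbest)) return true;
    for (int j = 0; j < m; ++j)
      if (j != jbest && take_step(i, j)) return true;
    return false;
  }
};

}  // namespace

// Sequential minimal optimization for the soft-margin SVM dual
//   min_b  -sum(b) + 0.5 * b' (yy' * K) b,   0 <= b_i <= C,  sum(b_i y_i) = 0
// over a precomputed kernel matrix. Deterministic: outer passes visit
// indices in order; the partner is the maximal-|E_i - E_j| index with a
// full-scan fallback.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-6, int max_updates = 100000) {
  Smo s(K, y, C, tol);
  int updates = 0;
  bool converged = false;
  while (updates < max_updates) {
    int viol = 0, changed = 0;
    for (int i = 0; i < s.m && updates < max_updates; ++i) {
      if (!s.violates(i)) continue;
      ++viol;
      if (s.examine(i)) { ++changed; ++updates; }
    }
    if (viol == 0) { converged = true; break; }
    if (changed == 0) break;  // violations remain but no progressing step
  }
  return List::create(_["alpha"] = NumericVector(s.a.begin(), s.a.end()),
                      _["b"] = s.b, _["updates"] = updates,
                      _["converged"] = converged);
}
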
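#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// kernel types: 0 = linear, 1 = polynomial, 2 = rbf
static inline double kernel_ij(const NumericMatrix& X, int i, int j,
                               int ktype, double g, double c0, double deg) {
  const int n = X.ncol();
  double s = 0.0;
  if (ktype == 2) {
    for (int k = 0; k < n; ++k) {
      const double d = X(i, k) - X(j, k);
      s += d * d;
    }
    return std::exp(-g * s);
  }
  for (int k = 0; k < n; ++k) s += X(i, k) * X(j, k);
  if (ktype == 0) return s;
  return std::pow(s + c0, deg);
}

// Soft-margin SVM dual trained by sequential minimal optimization
// (Platt-style pair selection with an error cache). Returns the dual
// variables, the bias (mean over free support vectors, falling back to all
// support vectors, then to the internal running threshold), the dual
// objective value and convergence information.
// [[Rcpp::export]]
List smo_fit(NumericMatrix X, NumericVector y, double C, int ktype,
             double g, double c0, double deg, double tol, int max_sweeps) {
  const int m = X.nrow();
  NumericMatrix K(m, m);
  for (int i = 0; i < m; ++i)
    for (int j = i; j < m; ++j)
      K(i, j) = K(j, i) = kernel_ij(X, i, j, ktype, g, c0, deg);

  std::vector<double> alpha(m, 0.0), E(m);
  double b = 0.0;
  for (int i = 0; i < m; ++i) E[i] = -y[i]; // f = 0 initially

  const double eps = 1e-12;

  auto take_step = [&](int i1, int i2) -> int {
    if (i1 == i2) return 0;
    const double a1 = alpha[i1], a2 = alpha[i2];
    const double y1 = y[i1], y2 = y[i2];
    const double E1 = E[i1], E2 = E[i2];
    const double s = y1 * y2;
    double L, H;
    if (s > 0) { L = std::max(0.0, a1 + a2 - C); H = std::min(C, a1 + a2); }
    else       { L = std::max(0.0, a2 - a1);     H = std::min(C, C + a2 - a1); }
    if (H - L < eps) return 0;
    const double k11 = K(i1, i1), k12 = K(i1, i2), k22 = K(i2, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    double a2new;
    if (eta > eps) {
      a2new = a2 + y2 * (E1 - E2) / eta;
      if (a2new < L) a2new = L;
      else if (a2new > H) a2new = H;
    } else {
      // zero curvature along the pair direction: the dual is linear in
      // a2, so move to the bound the directional derivative points at
      const double slope = y2 * (E1 - E2);
      if (slope > 1e-3 * tol) a2new = H;
      else if (slope < -1e-3 * tol) a2new = L;
      else return 0;
    }
    if (std::fabs(a2new - a2) < eps * (a2new + a2 + eps)) return 0;
    const double a1new = a1 + s * (a2 - a2new);
    const double b1 = b - E1 - y1 * (a1new - a1) * k11 - y2 * (a2new - a2) * k12;
    const double b2 = b - E2 - y1 * (a1new - a1) * k12 - y2 * (a2new - a2) * k22;
    double bnew;
    if (a1new > eps && a1new < C - eps) bnew = b1;
    else if (a2new > eps && a2new < C - eps) bnew = b2;
    else bnew = 0.5 * (b1 + b2);
    const double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
    for (int i = 0; i < m; ++i)
      E[i] += d1 * K(i1, i) + d2 * K(i2, i) + (bnew - b);
    alpha[i1] = a1new;
    alpha[i2] = a2new;
    b = bnew;
    return 1;
  };

  auto examine = [&](int i2) -> int {
    const double y2 = y[i2], a2 = alpha[i2], E2 = E[i2];
    const double r2 = E2 * y2;
    if (!((r2 < -tol && a2 < C - eps) || (r2 > tol && a2 > eps))) return 0;
    // heuristic 1: maximize |E1 - E2| over non-bound points
    int best = -1;
    double bestgap = 0.0;
    for (int i = 0; i < m; ++i) {
      if (alpha[i] > eps && alpha[i] < C - eps) {
        const double gap = std::fabs(E[i] - E2);
        if (gap > bestgap) { bestgap = gap; best = i; }
      }
    }
    if (best >= 0 && take_step(best, i2)) return 1;
    // heuristic 2: sweep non-bound points from a deterministic offset
    for (int k = 0; k < m; ++k) {
      const int i1 = (i2 + 1 + k) % m;
      if (alpha[i1] > eps && alpha[i1] < C - eps && take_step(i1, i2)) return 1;
    }
    // heuristic 3: sweep everything
    for (int k = 0; k < m; ++k) {
      const int i1 = (i2 + 1 + k) % m;
      if (take_step(i1, i2)) return 1;
    }
    return 0;
  };

  bool examine_all = true;
  int num_changed = 0, sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    ++sweeps;
    num_changed = 0;
    for (int i = 0; i < m; ++i) {
      if (examine_all || (alpha[i] > eps && alpha[i] < C - eps))
        num_changed += examine(i);
    }
    if (examine_all) {
      if (num_changed == 0) { converged = true; break; }
      examine_all = false;
    } else if (num_changed == 0) {
      examine_all = true;
    }
  }

  // dual objective W(alpha) = sum(alpha) - 1/2 sum_ij a_i a_j y_i y_j K_ij
  double obj = 0.0;
  for (int i = 0; i < m; ++i) obj += alpha[i];
  for (int i = 0; i < m; ++i) {
    if (alpha[i] == 0.0) continue;
    for (int j = 0; j < m; ++j) {
      if (alpha[j] == 0.0) continue;
      obj -= 0.5 * alpha[i] * alpha[j] * y[i] * y[j] * K(i, j);
    }
  }

  // bias: mean over free support vectors, else mean over all SVs
  const double sv_tol = 1e-8;
  std::vector<int> sv, freesv;
  for (int i = 0; i < m; ++i) {
    if (alpha[i] > sv_tol) {
      sv.push_back(i);
      if (alpha[i] < C - sv_tol) freesv.push_back(i);
    }
  }
  const std::vector<int>& bset = freesv.empty() ? sv : freesv;
  if (!bset.empty()) {
    double bsum = 0.0;
    for (int idx : bset) {
      double f0 = 0.0;
      for (int j : sv) f0 += alpha[j] * y[j] * K(j, idx);
      bsum += y[idx] - f0;
    }
    b = bsum / bset.size();
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
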
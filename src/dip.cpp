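#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dip statistic of an empirical CDF: the sup-norm distance from the ECDF to
// the closest unimodal (convex-then-concave, continuous) CDF, computed by
// bisection on the distance d. At a given d the ECDF induces a corridor
//   lo_i = max(0, F(x_i) - d),  hi_i = min(1, F(x_i^-) + d)
// at each distinct sample value x_i. A unimodal CDF within d exists iff some
// mode knot m admits a value v at x_m such that (i) a convex nondecreasing
// function fits the corridor on knots 1..m with value v at m and (ii) a
// concave nondecreasing one fits knots m..n with value v at m. Corridor
// feasibility uses the greatest convex minorant of the upper bounds (the
// largest convex function under hi), monotonised, which must clear lo; the
// concave side is the point reflection of the same check. The shared value v
// is located by bisection (the convex-feasible v form an upper interval, the
// concave-feasible v a lower interval).

struct DipWork {
  std::vector<double> lo, hi, env;
  std::vector<int> st;
};

// Longest feasible prefix of the unpinned convex corridor problem.
// hi must be nondecreasing (true for hi = min(1, F^- + d)).
static int max_feasible_prefix(const std::vector<double>& x,
                               const std::vector<double>& lo,
                               const std::vector<double>& hi,
                               std::vector<int>& st) {
  const int K = (int)x.size();
  st.clear();
  int M = 0;
  for (int m = 0; m < K; ++m) {
    if (lo[m] > hi[m]) break;
    while (st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      if ((hi[b] - hi[a]) * (x[m] - x[b]) >= (hi[m] - hi[b]) * (x[b] - x[a]))
        st.pop_back();
      else break;
    }
    bool ok = true;
    if (!st.empty()) {
      int t = st.back();
      double dx = x[m] - x[t];
      for (int j = t + 1; j < m; ++j) {
        double v = hi[t] + (hi[m] - hi[t]) * (x[j] - x[t]) / dx;
        if (v < lo[j]) { ok = false; break; }
      }
    }
    if (!ok) break;
    st.push_back(m);
    M = m + 1;
  }
  return M;
}

// Convex corridor feasibility on knots [0..m] with the box at m pinned to v.
// General version: computes the monotonised greatest convex minorant of the
// (pinned) upper bounds and checks it clears the lower bounds.
static bool pinned_convex(const double* x, const double* lo, const double* hi,
                          int m, double v, DipWork& w) {
  const int K = m + 1;
  double lom = v, him = v;
  if (lo[m] > v || v > hi[m]) return false;
  for (int i = 0; i < m; ++i) if (lo[i] > hi[i]) return false;
  w.st.clear();
  w.env.resize(K);
  for (int i = 0; i < K; ++i) {
    double hii = (i == m) ? him : hi[i];
    while (w.st.size() >= 2) {
      int a = w.st[w.st.size() - 2], b = w.st[w.st.size() - 1];
      double hb = (b == m) ? him : hi[b], ha = (a == m) ? him : hi[a];
      if ((hb - ha) * (x[i] - x[b]) >= (hii - hb) * (x[b] - x[a]))
        w.st.pop_back();
      else break;
    }
    w.st.push_back(i);
  }
  // hull values at every knot
  for (size_t s = 0; s + 1 < w.st.size(); ++s) {
    int a = w.st[s], b = w.st[s + 1];
    double ha = (a == m) ? him : hi[a], hb = (b == m) ? him : hi[b];
    w.env[a] = ha;
    for (int j = a + 1; j < b; ++j)
      w.env[j] = ha + (hb - ha) * (x[j] - x[a]) / (x[b] - x[a]);
  }
  w.env[w.st.back()] = (w.st.back() == m) ? him : hi[w.st.back()];
  // monotonise (largest convex *nondecreasing* minorant) and compare to lo
  double run = w.env[K - 1];
  for (int i = K - 1; i >= 0; --i) {
    if (w.env[i] < run) run = w.env[i];
    double loi = (i == m) ? lom : lo[i];
    if (run < loi) return false;
  }
  return true;
}

static bool coupled_at_mode(const std::vector<double>& x, DipWork& w,
                            const std::vector<double>& xr,
                            const std::vector<double>& lor,
                            const std::vector<double>& hir, DipWork& wr,
                            int K, int m) {
  double a = w.lo[m], b = w.hi[m];
  if (a > b) return false;
  int mr = K - 1 - m;
  for (int it = 0; it < 60; ++it) {
    double v = 0.5 * (a + b);
    bool cf = pinned_convex(x.data(), w.lo.data(), w.hi.data(), m, v, w);
    bool gf = pinned_convex(xr.data(), lor.data(), hir.data(), mr, -v, wr);
    if (cf && gf) return true;
    if (!cf && !gf) return false;         // convex needs larger v, concave smaller
    if (!cf) a = v; else b = v;
  }
  return false;
}

static bool feasible_at(const std::vector<double>& x,
                        const std::vector<double>& Fp,
                        const std::vector<double>& Fm,
                        double d, DipWork& w,
                        std::vector<double>& xr, std::vector<double>& lor,
                        std::vector<double>& hir, DipWork& wr,
                        int& hint) {
  const int K = (int)x.size();
  w.lo.resize(K); w.hi.resize(K);
  for (int i = 0; i < K; ++i) {
    w.lo[i] = std::max(0.0, Fp[i] - d);
    w.hi[i] = std::min(1.0, Fm[i] + d);
  }
  int M1 = max_feasible_prefix(x, w.lo, w.hi, w.st);
  if (M1 == 0) return false;
  // point reflection: concave suffix problem -> convex prefix problem
  xr.resize(K); lor.resize(K); hir.resize(K);
  for (int i = 0; i < K; ++i) {
    xr[i] = -x[K - 1 - i];
    hir[i] = -w.lo[K - 1 - i];
    lor[i] = -w.hi[K - 1 - i];
  }
  int M1r = max_feasible_prefix(xr, lor, hir, wr.st);
  if (M1r == 0) return false;
  int M2 = K - M1r;                       // 0-based smallest feasible suffix start
  if (M2 > M1 - 1) return false;
  // coupled check: a shared mode value v must exist at some knot m.
  // The hint (mode that worked at the previous, larger d) usually succeeds.
  if (hint >= M2 && hint <= M1 - 1 &&
      coupled_at_mode(x, w, xr, lor, hir, wr, K, hint))
    return true;
  for (int m = M2; m <= M1 - 1; ++m) {
    if (m == hint) continue;
    if (coupled_at_mode(x, w, xr, lor, hir, wr, K, m)) { hint = m; return true; }
  }
  return false;
}

// x: distinct ascending sample values; Fp: ECDF at x_i; Fm: ECDF just left of x_i.
// [[Rcpp::export(name = ".dip_ecdf_cpp")]]
double dip_ecdf_cpp(NumericVector x, NumericVector Fp, NumericVector Fm) {
  std::vector<double> xs(x.begin(), x.end());
  std::vector<double> fp(Fp.begin(), Fp.end());
  std::vector<double> fm(Fm.begin(), Fm.end());
  DipWork w, wr;
  std::vector<double> xr, lor, hir;
  int hint = -1;
  double a = 0.0, b = 0.5;
  for (int it = 0; it < 60 && (b - a) > 1e-14; ++it) {
    double d = 0.5 * (a + b);
    if (feasible_at(xs, fp, fm, d, w, xr, lor, hir, wr, hint)) b = d; else a = d;
  }
  return b;
}
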
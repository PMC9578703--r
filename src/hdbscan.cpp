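#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double ptdist(const NumericMatrix &X, int i, int j, bool manhattan) {
  double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1);
  if (manhattan) return std::abs(dx) + std::abs(dy);
  return std::sqrt(dx * dx + dy * dy);
}

// Core distances (distance to the min_samples-th nearest neighbour, the point
// itself counted) and the minimum spanning tree of the mutual-reachability
// graph, mrd(a,b) = max(core_a, core_b, d(a,b)). Prim's algorithm, O(n^2),
// distances computed on the fly so no n x n matrix is held.
// [[Rcpp::export]]
List mrd_mst_cpp(NumericMatrix X, int min_samples, bool manhattan) {
  const int n = X.nrow();
  NumericVector core(n);
  {
    std::vector<double> d(n);
    int k = std::min(min_samples, n) - 1; // 0-based rank; d[i][i] = 0 included
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) d[j] = ptdist(X, i, j, manhattan);
      std::nth_element(d.begin(), d.begin() + k, d.end());
      core[i] = d[k];
    }
  }
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, -1);
  std::vector<bool> used(n, false);
  IntegerVector ea(n - 1), eb(n - 1);
  NumericVector ew(n - 1);
  int cur = 0;
  used[0] = true;
  for (int step = 0; step < n - 1; ++step) {
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      double w = ptdist(X, cur, j, manhattan);
      double m = std::max(w, std::max((double)core[cur], (double)core[j]));
      if (m < best[j]) { best[j] = m; from[j] = cur; }
    }
    double mn = R_PosInf; int nxt = -1;
    for (int j = 0; j < n; ++j)
      if (!used[j] && best[j] < mn) { mn = best[j]; nxt = j; }
    ea[step] = from[nxt] + 1;
    eb[step] = nxt + 1;
    ew[step] = mn;
    used[nxt] = true;
    cur = nxt;
  }
  return List::create(_["core"] = core, _["from"] = ea, _["to"] = eb,
                      _["weight"] = ew);
}

// For each point i (in placement order), index of the nearest point among
// 1..i-1 (squared euclidean); NA for the first point. Used by the
// neighbour-copying species assignment in the synthetic-city generator.
// [[Rcpp::export]]
IntegerVector seq_nearest_cpp(NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  out[0] = NA_INTEGER;
  for (int i = 1; i < n; ++i) {
    double bd = R_PosInf; int bj = 0;
    for (int j = 0; j < i; ++j) {
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1);
      double d = dx * dx + dy * dy;
      if (d < bd) { bd = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
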
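#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Accumulate per-tree co-leaf counts scaled by `w` into the upper triangle
// of `o` (column-major n x n buffer).
static void accumulate_counts(const IntegerMatrix &nodes, double w,
                              double *o, int n) {
  const int B = nodes.ncol();
  std::unordered_map<int, std::vector<int>> groups;
  for (int b = 0; b < B; ++b) {
    groups.clear();
    const int *col = &nodes(0, b);
    for (int i = 0; i < n; ++i) groups[col[i]].push_back(i);
    for (auto &kv : groups) {
      std::vector<int> &g = kv.second;
      const int m = g.size();
      for (int c = 0; c < m; ++c) {
        double *ocol = o + (size_t)g[c] * n;   // column g[c]
        for (int a = 0; a <= c; ++a) ocol[g[a]] += w;
      }
    }
  }
}

// mirror the filled upper triangle into the lower one
static void mirror_upper(double *o, int n) {
  for (int j = 0; j < n; ++j) {
    const double *cj = o + (size_t)j * n;
    for (int i = 0; i < j; ++i) o[(size_t)i * n + j] = cj[i];
  }
}

// Co-leaf counts across trees: out(i,j) = #{b : nodes(i,b) == nodes(j,b)}.
// Groups rows by terminal node per tree, so the cost is the sum of squared
// leaf sizes rather than n^2 per tree; the result equals the naive count.
// [[Rcpp::export(.prox_counts_cpp)]]
NumericMatrix prox_counts_cpp(IntegerMatrix nodes, bool zero_diag = false) {
  const int n = nodes.nrow();
  NumericMatrix out(n, n);
  double *o = out.begin();
  accumulate_counts(nodes, 1.0, o, n);
  mirror_upper(o, n);
  if (zero_diag)
    for (int i = 0; i < n; ++i) o[(size_t)i * n + i] = 0.0;
  return out;
}

// Fused dual-forest proximity: 0.5 * (counts_T / B_T + counts_Y / B_Y)
// with zeroed diagonal, in a single accumulation buffer.
// [[Rcpp::export(.prox_dual_cpp)]]
NumericMatrix prox_dual_cpp(IntegerMatrix nodes_t, IntegerMatrix nodes_y) {
  const int n = nodes_t.nrow();
  if (nodes_y.nrow() != n) stop("node matrices disagree on n");
  NumericMatrix out(n, n);
  double *o = out.begin();
  accumulate_counts(nodes_t, 0.5 / nodes_t.ncol(), o, n);
  accumulate_counts(nodes_y, 0.5 / nodes_y.ncol(), o, n);
  mirror_upper(o, n);
  for (int i = 0; i < n; ++i) o[(size_t)i * n + i] = 0.0;
  return out;
}

// Element-wise average of two proximity matrices with zeroed diagonal.
// [[Rcpp::export(.prox_average_cpp)]]
NumericMatrix prox_average_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow();
  NumericMatrix out(n, A.ncol());
  const double *a = A.begin(), *b = B.begin();
  double *o = out.begin();
  const size_t len = (size_t)A.nrow() * A.ncol();
  for (size_t k = 0; k < len; ++k) o[k] = 0.5 * (a[k] + b[k]);
  for (int i = 0; i < n; ++i) o[(size_t)i * n + i] = 0.0;
  return out;
}

// Proximity-weighted imputation values for the originally missing cells.
// Continuous columns: weighted mean of donors' current values. Binary
// columns: category maximizing observed-proportion-weighted support, ties
// to category 0. Rows with zero total proximity get NA (caller applies the
// uniform-donor fallback). Observed cells are returned untouched. M must be
// symmetric (proximities are), so row i is read as contiguous column i.
// [[Rcpp::export(.prox_update_cpp)]]
NumericMatrix prox_update_cpp(NumericMatrix M, NumericMatrix X,
                              IntegerMatrix S, LogicalVector binary,
                              NumericVector p1) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out = clone(X);
  const double *m = M.begin();
  std::vector<double> rs(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *mi = m + (size_t)i * n;
    double acc = 0.0;
    for (int k = 0; k < n; ++k) acc += mi[k];
    rs[i] = acc;
  }
  for (int j = 0; j < p; ++j) {
    const bool bin = binary[j];
    const double *xj = &X(0, j);
    for (int i = 0; i < n; ++i) {
      if (S(i, j) != 1) continue;
      if (rs[i] <= 0.0) {
        out(i, j) = NA_REAL;
        continue;
      }
      const double *mi = m + (size_t)i * n;
      if (!bin) {
        double acc = 0.0;
        for (int k = 0; k < n; ++k) acc += mi[k] * xj[k];
        out(i, j) = acc / rs[i];
      } else {
        double s1 = 0.0;
        for (int k = 0; k < n; ++k)
          if (xj[k] == 1.0) s1 += mi[k];
        const double w1 = s1 / rs[i], w0 = (rs[i] - s1) / rs[i];
        out(i, j) = (p1[j] * w1 > (1.0 - p1[j]) * w0) ? 1.0 : 0.0;
      }
    }
  }
  return out;
}
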
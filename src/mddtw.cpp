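// Multidimensional dynamic time warping.
//
// Local cost between frame i of A and frame j of B is the Euclidean
// distance over the selected feature columns. Step pattern: (1,0), (0,1),
// (1,1), all with weight 1; no warping window. Ties among predecessors are
// broken diagonal > up > left, which also makes the reported path length
// deterministic. The normalized distance divides the accumulated cost by
// the number of path steps.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double local_cost(const double* a, const double* b,
                                const std::vector<int>& cols,
                                int La, int Lb, int i, int j) {
  double s = 0.0;
  for (size_t f = 0; f < cols.size(); ++f) {
    const double d = a[i + (size_t)La * cols[f]] - b[j + (size_t)Lb * cols[f]];
    s += d * d;
  }
  return std::sqrt(s);
}

// Accumulated-cost DP; returns distance and optimal-path length (#cells).
static void dtw_core(const double* a, const double* b, int La, int Lb,
                     const std::vector<int>& cols,
                     double& dist, int& plen) {
  std::vector<double> prev(Lb), cur(Lb);
  std::vector<int> sprev(Lb), scur(Lb);
  for (int j = 0; j < Lb; ++j) {
    prev[j] = (j == 0 ? 0.0 : prev[j - 1]) + local_cost(a, b, cols, La, Lb, 0, j);
    sprev[j] = j + 1;
  }
  for (int i = 1; i < La; ++i) {
    cur[0] = prev[0] + local_cost(a, b, cols, La, Lb, i, 0);
    scur[0] = i + 1;
    for (int j = 1; j < Lb; ++j) {
      const double c = local_cost(a, b, cols, La, Lb, i, j);
      double best = prev[j - 1];            // diagonal
      int bsteps = sprev[j - 1];
      if (prev[j] < best) { best = prev[j]; bsteps = sprev[j]; }       // up
      if (cur[j - 1] < best) { best = cur[j - 1]; bsteps = scur[j - 1]; } // left
      cur[j] = best + c;
      scur[j] = bsteps + 1;
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  dist = prev[Lb - 1];
  plen = sprev[Lb - 1];
}

static std::vector<int> as_cols(const IntegerVector& cols1, int nc) {
  std::vector<int> cols(cols1.size());
  for (int f = 0; f < cols1.size(); ++f) {
    if (cols1[f] < 1 || cols1[f] > nc) stop("feature column index out of range");
    cols[f] = cols1[f] - 1;
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector mddtw_dist_cpp(NumericMatrix A, NumericMatrix B,
                             IntegerVector cols1) {
  if (A.ncol() != B.ncol()) stop("feature dimension mismatch");
  if (A.nrow() < 1 || B.nrow() < 1) stop("empty series");
  std::vector<int> cols = as_cols(cols1, A.ncol());
  double d; int n;
  dtw_core(REAL(A), REAL(B), A.nrow(), B.nrow(), cols, d, n);
  return NumericVector::create(_["distance"] = d, _["path_length"] = (double)n);
}

// Full DP matrix with backtracking; used where the warping path itself is
// needed. Same step pattern and tie-breaks as dtw_core.
// [[Rcpp::export]]
List mddtw_align_cpp(NumericMatrix A, NumericMatrix B, IntegerVector cols1) {
  if (A.ncol() != B.ncol()) stop("feature dimension mismatch");
  const int La = A.nrow(), Lb = B.nrow();
  if (La < 1 || Lb < 1) stop("empty series");
  std::vector<int> cols = as_cols(cols1, A.ncol());
  std::vector<double> D((size_t)La * Lb);
  std::vector<signed char> from((size_t)La * Lb); // 0 start, 1 diag, 2 up, 3 left
  const double* a = REAL(A); const double* b = REAL(B);
  for (int i = 0; i < La; ++i) {
    for (int j = 0; j < Lb; ++j) {
      const double c = local_cost(a, b, cols, La, Lb, i, j);
      const size_t ij = (size_t)i * Lb + j;
      if (i == 0 && j == 0) { D[ij] = c; from[ij] = 0; }
      else if (i == 0) { D[ij] = D[ij - 1] + c; from[ij] = 3; }
      else if (j == 0) { D[ij] = D[ij - Lb] + c; from[ij] = 2; }
      else {
        double best = D[ij - Lb - 1]; signed char f = 1;
        if (D[ij - Lb] < best) { best = D[ij - Lb]; f = 2; }
        if (D[ij - 1] < best) { best = D[ij - 1]; f = 3; }
        D[ij] = best + c; from[ij] = f;
      }
    }
  }
  std::vector<int> pi, pj;
  int i = La - 1, j = Lb - 1;
  while (true) {
    pi.push_back(i + 1); pj.push_back(j + 1);
    const signed char f = from[(size_t)i * Lb + j];
    if (f == 0) break;
    if (f == 1) { --i; --j; }
    else if (f == 2) { --i; }
    else { --j; }
  }
  const int n = (int)pi.size();
  IntegerMatrix path(n, 2);
  for (int k = 0; k < n; ++k) {
    path(k, 0) = pi[n - 1 - k];
    path(k, 1) = pj[n - 1 - k];
  }
  const double d = D[(size_t)La * Lb - 1];
  return List::create(_["distance"] = d, _["path"] = path,
                      _["normalized_distance"] = d / n);
}

// Distances from one query to every member of a bank.
// [[Rcpp::export]]
NumericVector mddtw_query_cpp(NumericMatrix Q, List bank, IntegerVector cols1,
                              bool normalize_by_path) {
  NumericVector out(bank.size());
  std::vector<int> cols = as_cols(cols1, Q.ncol());
  for (int m = 0; m < bank.size(); ++m) {
    NumericMatrix B = bank[m];
    if (B.ncol() != Q.ncol()) stop("feature dimension mismatch in bank");
    double d; int n;
    dtw_core(REAL(Q), REAL(B), Q.nrow(), B.nrow(), cols, d, n);
    out[m] = normalize_by_path ? d / n : d;
  }
  return out;
}

// Symmetric pairwise distance matrix over a list of series; the hot loop
// of leave-one-out scoring inside backward elimination.
// [[Rcpp::export]]
NumericMatrix mddtw_pairwise_cpp(List series, IntegerVector cols1,
                                 bool normalize_by_path) {
  const int m = series.size();
  if (m < 1) stop("empty series list");
  NumericMatrix first = series[0];
  std::vector<int> cols = as_cols(cols1, first.ncol());
  NumericMatrix out(m, m);
  for (int u = 0; u < m; ++u) {
    NumericMatrix A = series[u];
    for (int v = u + 1; v < m; ++v) {
      NumericMatrix B = series[v];
      if (A.ncol() != B.ncol()) stop("feature dimension mismatch in series list");
      double d; int n;
      dtw_core(REAL(A), REAL(B), A.nrow(), B.nrow(), cols, d, n);
      const double val = normalize_by_path ? d / n : d;
      out(u, v) = val;
      out(v, u) = val;
    }
  }
  return out;
}
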
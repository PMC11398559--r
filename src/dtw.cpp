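#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with squared-difference local cost, step set
// {(1,0),(0,1),(1,1)}, both endpoints constrained, optional Sakoe-Chiba
// band (half-width `band`; band < 0 means unconstrained).  The accumulated
// cost at (n-1, m-1) is the squared DTW distance.

static double dtw_fill(const NumericVector& x, const NumericVector& y,
                       int band, NumericMatrix* acc_out) {
  const int n = x.size(), m = y.size();
  NumericMatrix acc(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (band >= 0 && std::abs(i - j) > band) {
        acc(i, j) = R_PosInf;
        continue;
      }
      double d = x[i] - y[j];
      d *= d;
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0 && j > 0 && acc(i - 1, j - 1) < best) best = acc(i - 1, j - 1);
        if (i > 0 && acc(i - 1, j) < best) best = acc(i - 1, j);
        if (j > 0 && acc(i, j - 1) < best) best = acc(i, j - 1);
      }
      acc(i, j) = d + best;
    }
  }
  if (acc_out) *acc_out = acc;
  return acc(n - 1, m - 1);
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y, int band) {
  return dtw_fill(x, y, band, NULL);
}

// Optimal warping path, 1-based index pairs from (1,1) to (n,m).
// Backtracking tie-break is deterministic: diagonal, then (i-1,j), then (i,j-1).
// [[Rcpp::export]]
IntegerMatrix dtw_path_cpp(NumericVector x, NumericVector y, int band) {
  NumericMatrix acc;
  dtw_fill(x, y, band, &acc);
  int i = x.size() - 1, j = y.size() - 1;
  std::vector<int> pi, pj;
  pi.push_back(i);
  pj.push_back(j);
  while (i > 0 || j > 0) {
    double best = R_PosInf;
    int bi = i, bj = j;
    if (i > 0 && j > 0 && acc(i - 1, j - 1) < best) { best = acc(i - 1, j - 1); bi = i - 1; bj = j - 1; }
    if (i > 0 && acc(i - 1, j) < best)              { best = acc(i - 1, j);     bi = i - 1; bj = j;     }
    if (j > 0 && acc(i, j - 1) < best)              { best = acc(i, j - 1);     bi = i;     bj = j - 1; }
    i = bi;
    j = bj;
    pi.push_back(i);
    pj.push_back(j);
  }
  const int L = (int)pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k] + 1;
    path(k, 1) = pj[L - 1 - k] + 1;
  }
  return path;
}

// Cross distance matrix (DTW distance, i.e. sqrt of accumulated cost)
// between rows of A and rows of B.
// [[Rcpp::export]]
NumericMatrix dtw_cdist_cpp(NumericMatrix A, NumericMatrix B, int band) {
  const int na = A.nrow(), nb = B.nrow();
  NumericMatrix D(na, nb);
  for (int a = 0; a < na; ++a) {
    NumericVector xa = A(a, _);
    for (int b = 0; b < nb; ++b) {
      NumericVector yb = B(b, _);
      D(a, b) = std::sqrt(dtw_fill(xa, yb, band, NULL));
    }
  }
  return D;
}

// Symmetric pairwise DTW distance matrix between rows of A.
// [[Rcpp::export]]
NumericMatrix dtw_pdist_cpp(NumericMatrix A, int band) {
  const int n = A.nrow();
  NumericMatrix D(n, n);
  for (int a = 0; a < n; ++a) {
    NumericVector xa = A(a, _);
    for (int b = a + 1; b < n; ++b) {
      NumericVector yb = A(b, _);
      double d = std::sqrt(dtw_fill(xa, yb, band, NULL));
      D(a, b) = d;
      D(b, a) = d;
    }
  }
  return D;
}
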
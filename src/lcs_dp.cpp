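#include <Rcpp.h>
using namespace Rcpp;

// Fill the (m+1)x(n+1) LCS dynamic-programming matrix from a pairwise
// token-similarity matrix. The diagonal branch fires when sim > eps
// (or >= eps when inclusive), otherwise c[i][j] = max(c[i-1][j], c[i][j-1]).

// [[Rcpp::export]]
IntegerMatrix lcs_dp_fill(NumericMatrix sim, double eps, bool inclusive) {
  int m = sim.nrow(), n = sim.ncol();
  IntegerMatrix c(m + 1, n + 1);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sim(i - 1, j - 1);
      bool hit = inclusive ? (s >= eps) : (s > eps);
      if (hit) {
        c(i, j) = c(i - 1, j - 1) + 1;
      } else {
        int up = c(i - 1, j), left = c(i, j - 1);
        c(i, j) = up >= left ? up : left;
      }
    }
  }
  return c;
}

// Length-only variant with O(n) memory, used by the batch scorer.

// [[Rcpp::export]]
int lcs_dp_length(NumericMatrix sim, double eps, bool inclusive) {
  int m = sim.nrow(), n = sim.ncol();
  if (m == 0 || n == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      double s = sim(i - 1, j - 1);
      bool hit = inclusive ? (s >= eps) : (s > eps);
      if (hit) {
        cur[j] = prev[j - 1] + 1;
      } else {
        cur[j] = prev[j] >= cur[j - 1] ? prev[j] : cur[j - 1];
      }
    }
    std::swap(prev, cur);
  }
  return prev[n];
}
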
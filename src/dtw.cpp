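#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping with absolute-difference local cost and
// symmetric steps (match / insert / delete), no window constraint.

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty series");
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Full DP table plus backtracked optimal alignment path.
// Ties prefer the diagonal step, then the step consuming a, then b
// (deterministic path for barycenter averaging).

// [[Rcpp::export]]
IntegerMatrix dtw_path_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty series");
  NumericMatrix D(n + 1, m + 1);
  std::fill(D.begin(), D.end(), R_PosInf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double cost = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = cost + best;
    }
  }
  std::vector<int> pi, pj;
  int i = n, j = m;
  pi.push_back(i); pj.push_back(j);
  while (i > 1 || j > 1) {
    if (i == 1) { --j; }
    else if (j == 1) { --i; }
    else {
      double d = D(i - 1, j - 1), u = D(i - 1, j), l = D(i, j - 1);
      if (d <= u && d <= l) { --i; --j; }
      else if (u <= l) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {        // reverse into start-to-end order
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return path;
}
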
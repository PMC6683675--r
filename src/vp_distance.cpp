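#include <Rcpp.h>
using namespace Rcpp;

// Victor-Purpura spike-time distance by the standard dynamic program.
// Edit costs: insert/delete a spike = 1, move a spike by dt = q*|dt|.
static double vp_pair(const double* a, int n, const double* b, int m, double q) {
  if (n == 0) return (double)m;
  if (m == 0) return (double)n;
  // two-row DP; G[i][j] = cost of matching a[0..i) with b[0..j)
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = (double)j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = (double)i;
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::abs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".vp_pair_cpp")]]
double vp_pair_cpp(NumericVector a, NumericVector b, double q) {
  return vp_pair(a.begin(), a.size(), b.begin(), b.size(), q);
}

// All-pairs distance matrix for one cost parameter q.
// [[Rcpp::export(name = ".vp_matrix_cpp")]]
NumericMatrix vp_matrix_cpp(List trains, double q) {
  int n = trains.size();
  std::vector<NumericVector> tr(n);
  for (int i = 0; i < n; ++i) tr[i] = as<NumericVector>(trains[i]);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = vp_pair(tr[i].begin(), tr[i].size(), tr[j].begin(), tr[j].size(), q);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
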
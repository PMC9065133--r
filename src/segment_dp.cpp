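#include <Rcpp.h>
using namespace Rcpp;

// Exact dynamic-programming segmentation of a trace into piecewise
// constant levels. For each number of change points m = 0..max_cp the
// globally RSS-optimal segmentation is found; cost(i, j) of fitting one
// mean to y[i..j] comes from prefix sums in O(1).
//
// Returns, for each m: the minimal RSS and the change-point positions
// (last index of each segment except the final one, 0-based).
// [[Rcpp::export]]
List segment_dp_cpp(NumericVector y, int max_cp) {
  const int n = y.size();
  if (n < 1) stop("empty trace");
  if (max_cp < 0) stop("max_cp must be >= 0");
  if (max_cp > n - 1) max_cp = n - 1;

  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + y[i];
    S2[i + 1] = S2[i] + y[i] * y[i];
  }
  auto cost = [&](int i, int j) {  // inclusive 0-based segment [i, j]
    const double s = S[j + 1] - S[i];
    const double s2 = S2[j + 1] - S2[i];
    const int len = j - i + 1;
    return s2 - s * s / len;
  };

  const int M = max_cp;
  // D[m][j]: best RSS for y[0..j] using m change points
  std::vector< std::vector<double> > D(M + 1, std::vector<double>(n));
  std::vector< std::vector<int> > B(M + 1, std::vector<int>(n, -1));
  for (int j = 0; j < n; ++j) D[0][j] = cost(0, j);
  for (int m = 1; m <= M; ++m) {
    for (int j = 0; j < n; ++j) {
      double best = R_PosInf;
      int arg = -1;
      if (j >= m) {  // need at least m+1 points for m change points
        for (int i = m - 1; i < j; ++i) {
          const double v = D[m - 1][i] + cost(i + 1, j);
          if (v < best) { best = v; arg = i; }
        }
      }
      D[m][j] = best;
      B[m][j] = arg;
    }
  }

  NumericVector rss(M + 1);
  List cps(M + 1);
  for (int m = 0; m <= M; ++m) {
    rss[m] = std::max(D[m][n - 1], 0.0);
    IntegerVector cp(m);
    int j = n - 1;
    for (int mm = m; mm >= 1; --mm) {
      const int i = B[mm][j];
      cp[mm - 1] = i;
      j = i;
    }
    cps[m] = cp;
  }
  return List::create(_["rss"] = rss, _["changepoints"] = cps);
}
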
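#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Fisher optimal partition of sorted values into k contiguous
// classes minimising within-class sum of squared deviations. Ties in the
// optimum resolve to the smallest split indices (lexicographically
// smallest break vector). Returns the k-1 internal breaks as the maximum
// value of classes 1..k-1.
// [[Rcpp::export]]
NumericVector fisherJenksCpp(NumericVector sortedValues, int k) {
  const int n = sortedValues.size();
  if (k < 2 || n < k) stop("invalid Fisher-Jenks input");
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + sortedValues[i];
    cs2[i + 1] = cs2[i] + sortedValues[i] * sortedValues[i];
  }
  // ssd of values [i, j] inclusive, 0-based
  auto ssd = [&](int i, int j) {
    const double s = cs[j + 1] - cs[i];
    const double s2 = cs2[j + 1] - cs2[i];
    const int m = j - i + 1;
    double v = s2 - s * s / m;
    return v > 0 ? v : 0.0;
  };
  const double inf = std::numeric_limits<double>::infinity();
  // cost[c][j]: best cost of first j values in c+1 classes; split[c][j]:
  // 0-based start index of the last class in that optimum
  std::vector<std::vector<double>> cost(k, std::vector<double>(n + 1, inf));
  std::vector<std::vector<int>> split(k, std::vector<int>(n + 1, 0));
  for (int j = 1; j <= n; ++j) cost[0][j] = ssd(0, j - 1);
  for (int c = 1; c < k; ++c) {
    for (int j = c + 1; j <= n; ++j) {
      double best = inf;
      int bestS = c;
      for (int s = c; s < j; ++s) { // last class = values [s, j-1]
        if (cost[c - 1][s] == inf) continue;
        const double v = cost[c - 1][s] + ssd(s, j - 1);
        if (v < best) { // ascending s: first optimum = smallest split
          best = v;
          bestS = s;
        }
      }
      cost[c][j] = best;
      split[c][j] = bestS;
    }
  }
  NumericVector breaks(k - 1);
  int j = n;
  for (int c = k - 1; c >= 1; --c) {
    const int s = split[c][j];
    breaks[c - 1] = sortedValues[s - 1]; // max of class c (1-based)
    j = s;
  }
  return breaks;
}
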
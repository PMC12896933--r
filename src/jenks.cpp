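#include <Rcpp.h>
using namespace Rcpp;

// Exact Fisher dynamic program for natural-breaks classification.
// Minimises total within-class sum of squared deviations for k classes
// over sorted values x. Returns the index (1-based, into the sorted vector)
// of the first element of each class.
// [[Rcpp::export(name = ".jenks_dp")]]
IntegerVector jenks_dp(NumericVector x, int k) {
  int n = x.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  auto ssq = [&](int a, int b) { // 0-based inclusive [a, b]
    double s = cs[b + 1] - cs[a];
    double s2 = cs2[b + 1] - cs2[a];
    int m = b - a + 1;
    return s2 - s * s / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  // D[j][i]: min cost of splitting x[0..i] into j+1 classes
  std::vector<std::vector<double>> D(k, std::vector<double>(n, INF));
  std::vector<std::vector<int>> B(k, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) D[0][i] = ssq(0, i);
  for (int j = 1; j < k; ++j) {
    for (int i = j; i < n; ++i) {
      double best = INF;
      int bestm = j;
      for (int m = j; m <= i; ++m) { // class j starts at m
        double c = D[j - 1][m - 1] + ssq(m, i);
        if (c < best - 1e-12 ||
            (std::abs(c - best) <= 1e-12 && m < bestm)) { // tie: lowest boundary
          best = c;
          bestm = m;
        }
      }
      D[j][i] = best;
      B[j][i] = bestm;
    }
  }
  IntegerVector starts(k);
  int i = n - 1;
  for (int j = k - 1; j >= 1; --j) {
    starts[j] = B[j][i] + 1; // 1-based
    i = B[j][i] - 1;
  }
  starts[0] = 1;
  return starts;
}
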
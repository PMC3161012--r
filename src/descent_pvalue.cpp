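#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Exact P-value of the maximum-descent statistic of a hypergeometric random
// walk with m up and n down unit steps: the probability that a uniformly
// random arrangement of the steps shows a peak-to-subsequent-trough drop of
// at least k somewhere along the walk.
//
// Dynamic programme over step positions.  State: (u, d) where u is the
// number of up steps consumed and d = runningMax - currentHeight is the
// current deficit, truncated at k (paths reaching deficit k are absorbed
// and dropped from the survival mass).  Transition weights are the exact
// sequential-sampling probabilities of drawing an up or down step from the
// remaining pool, so the accumulated mass stays in [0,1] and never
// overflows even for walks with thousands of steps.
//
// Time O((m+n) * m * k), memory O(m * k).

// [[Rcpp::export]]
double descentPvalueCpp(int m, int n, int k) {
  if (m < 0 || n < 0 || k < 0)
    Rcpp::stop("m, n and k must be non-negative");
  if (k == 0) return 1.0;
  if (k > n) return 0.0;          // descent cannot exceed the down-step total
  const int T = m + n;
  std::vector< std::vector<double> > f(m + 1, std::vector<double>(k, 0.0));
  std::vector< std::vector<double> > g(m + 1, std::vector<double>(k, 0.0));
  f[0][0] = 1.0;
  for (int t = 0; t < T; ++t) {
    for (int u = 0; u <= m; ++u)
      std::fill(g[u].begin(), g[u].end(), 0.0);
    const double remaining = (double)(T - t);
    const int uLo = std::max(0, t - n), uHi = std::min(m, t);
    for (int u = uLo; u <= uHi; ++u) {
      const int upsLeft = m - u;
      const int downsLeft = n - (t - u);
      for (int d = 0; d < k; ++d) {
        const double w = f[u][d];
        if (w == 0.0) continue;
        if (upsLeft > 0)
          g[u + 1][d > 0 ? d - 1 : 0] += w * (upsLeft / remaining);
        if (downsLeft > 0 && d + 1 < k)
          g[u][d + 1] += w * (downsLeft / remaining);
        // a down step reaching deficit k is absorbed (descent achieved)
      }
    }
    f.swap(g);
  }
  double survive = 0.0;
  for (int d = 0; d < k; ++d) survive += f[m][d];
  double p = 1.0 - survive;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}
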
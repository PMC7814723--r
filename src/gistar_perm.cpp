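#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Conditional permutation pseudo p-values for the Getis-Ord Gi* statistic
// with binary weights and the self term (w_ii = 1).
//
// For zone i the value x_i is held fixed and the n_i neighbor values are
// drawn without replacement from the remaining n-1 values. Because the
// permuted arrangement keeps the same value multiset, the global mean and
// sd (and hence the Gi* denominator) are unchanged, so ranking |z| is
// equivalent to ranking |S_i - xbar * W_i| with S_i the weighted sum
// including self. Uses R's RNG, so set.seed() governs determinism.
// [[Rcpp::export(name = ".gistar_perm_p")]]
NumericVector gistar_perm_p(NumericVector x, List nbs, int n_perm) {
  const int n = x.size();
  NumericVector p(n);
  double xbar = mean(x);
  RNGScope scope;

  std::vector<int> pool(n - 1);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbs[i];
    const int ni = nb.size();
    if (ni == 0) { p[i] = NA_REAL; continue; }
    double s_obs = x[i];
    for (int k = 0; k < ni; ++k) s_obs += x[nb[k] - 1];
    const double center = xbar * (ni + 1);
    const double t_obs = std::fabs(s_obs - center);

    // pool of candidate indices excluding i
    int m = 0;
    for (int j = 0; j < n; ++j) if (j != i) pool[m++] = j;

    int count = 0;
    for (int rep = 0; rep < n_perm; ++rep) {
      // partial Fisher-Yates draw of ni indices without replacement
      double s = x[i];
      for (int k = 0; k < ni; ++k) {
        int r = k + (int)(unif_rand() * (m - k));
        if (r >= m) r = m - 1;
        int tmp = pool[k]; pool[k] = pool[r]; pool[r] = tmp;
        s += x[pool[k]];
      }
      if (std::fabs(s - center) >= t_obs) ++count;
    }
    p[i] = (1.0 + count) / (1.0 + n_perm);
  }
  return p;
}
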
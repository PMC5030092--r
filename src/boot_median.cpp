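#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of the first n elements of v; reorders v
static double median_inplace(std::vector<double> &v, int n) {
  int k = n / 2;
  std::nth_element(v.begin(), v.begin() + k, v.begin() + n);
  double hi = v[k];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + k);
  return (lo + hi) / 2.0;
}

// Resampling engine for the two-tailed bootstrap of medians.
//
// Pools test and matched values; in each resample draws a pseudo-test set
// of size n_test and a pseudo-matched set of size n_matched (with
// replacement when permute = false, by partial Fisher-Yates shuffle of the
// pool when permute = true) and counts resamples whose absolute
// median difference is >= threshold.  Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
double boot_median_count(NumericVector pool, int n_test, int n_matched,
                         double n_resamples, double threshold, bool permute) {
  int n = pool.size();
  if (permute && n_test + n_matched > n)
    stop("permutation scheme needs n_test + n_matched <= pool size");
  std::vector<double> a((size_t)std::max(n_test, 1));
  std::vector<double> b((size_t)std::max(n_matched, 1));
  std::vector<double> work(pool.begin(), pool.end());
  double count = 0;
  for (double r = 0; r < n_resamples; r++) {
    if (permute) {
      for (int i = 0; i < n_test + n_matched; i++) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(work[i], work[j]);
      }
      for (int i = 0; i < n_test; i++) a[i] = work[i];
      for (int i = 0; i < n_matched; i++) b[i] = work[n_test + i];
    } else {
      for (int i = 0; i < n_test; i++) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        a[i] = pool[j];
      }
      for (int i = 0; i < n_matched; i++) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        b[i] = pool[j];
      }
    }
    double d = median_inplace(a, n_test) - median_inplace(b, n_matched);
    if (std::abs(d) >= threshold) count += 1;
  }
  return count;
}
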
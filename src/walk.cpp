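#include <Rcpp.h>
using namespace Rcpp;

// Visit counts of a single long categorical walk. `cum` holds the damped
// transition matrix as row-wise cumulative sums, so each step is one
// uniform draw plus a binary search in the current row. Uses R's RNG so
// set.seed() controls the walk.
// [[Rcpp::export]]
NumericVector mc_walk_visits(NumericMatrix cum, double steps, int burnin) {
  const int n = cum.nrow();
  NumericVector visits(n);
  int state = (int)(unif_rand() * n);
  if (state >= n) state = n - 1;
  const double total = steps + burnin;
  for (double t = 0; t < total; t += 1.0) {
    const double u = unif_rand();
    int lo = 0, hi = n - 1;
    while (lo < hi) {              // first j with cum(state, j) >= u
      const int mid = (lo + hi) / 2;
      if (cum(state, mid) < u) lo = mid + 1; else hi = mid;
    }
    state = lo;
    if (t >= burnin) visits[state] += 1.0;
  }
  return visits;
}
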
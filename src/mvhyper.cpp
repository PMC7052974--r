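#include <Rcpp.h>
using namespace Rcpp;

// Multivariate hypergeometric draw via iterated conditional univariate
// hypergeometric sampling. `pool` holds integer-valued category counts
// (stored as doubles; every count and the pool total must stay below
// 2^31 for R's rhyper). Draws `k` items without replacement; if
// k >= sum(pool) the whole pool is returned.
// Uses R's RNG, so results are reproducible via set.seed().

// [[Rcpp::export]]
NumericVector mvhyper_cpp(NumericVector pool, double k) {
  const int n = pool.size();
  NumericVector out(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (pool[i] < 0) stop("negative count in pool");
    total += pool[i];
  }
  if (total > 2147483647.0) stop("pool total exceeds 2^31-1; cannot sample");
  if (k >= total) return clone(pool);
  double draws = k;
  double remaining = total;
  for (int i = 0; i < n; ++i) {
    if (draws <= 0) break;
    const double m = pool[i];
    remaining -= m;
    double x;
    if (remaining <= 0) {
      x = draws;  // last non-empty tail: take the rest
    } else {
      x = ::Rf_rhyper(m, remaining, draws);
    }
    out[i] = x;
    draws -= x;
  }
  return out;
}
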
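#include <Rcpp.h>
using namespace Rcpp;

// Draw registered counts per ToF bin under the non-paralyzable dead-time
// model: each of n_ext extractions deposits true counts Poisson(lambda[i])
// per bin, at most one count per bin per extraction can register, and after
// a registered count the extraction is blind for the following dead_bins
// bins. Because an extraction registers at most once inside any d-bin
// window, the number of extractions available at bin i is exactly
// n_ext - sum(A[i-d..i-1]) and A[i] | history ~ Binomial(n_avail, 1-exp(-lambda[i])).
//
// Sampling is by binomial inverse transform on one uniform per nonzero-rate
// bin: qbinom(u, n, p) is monotone in n, so for the same seed a run with
// dead_bins > 0 is pointwise <= the run with dead_bins = 0 (censoring only
// ever removes counts). Uses R's RNG: set.seed()-reproducible.
// [[Rcpp::export]]
IntegerVector censored_counts(NumericVector lambda, double n_ext, int dead_bins) {
  int n = lambda.size();
  IntegerVector out(n);
  RNGScope scope;
  double winsum = 0.0;
  for (int i = 0; i < n; ++i) {
    if (dead_bins > 0 && i > dead_bins) winsum -= out[i - dead_bins - 1];
    double n_avail = n_ext - (dead_bins > 0 ? winsum : 0.0);
    double a = 0.0;
    if (lambda[i] > 0.0) {
      double u = unif_rand();
      if (n_avail >= 1.0) {
        double p = -expm1(-lambda[i]);
        a = R::qbinom(u, std::floor(n_avail), p, 1, 0);
      }
    }
    out[i] = (int) a;
    if (dead_bins > 0) winsum += a;
  }
  return out;
}
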
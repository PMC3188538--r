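#include <Rcpp.h>
using namespace Rcpp;

// Recursion for the Lea-Coulson mutant-count pmf (compound Poisson with
// clone-size law q_j = 1/(j(j+1)); Panjer form of the Ma-Sandri-Sarkar
// algorithm, derived from the pgf exp(m*(1-z)ln(1-z)/z)):
//   p0 = exp(-m);  pn = (m/n) * sum_{j=0}^{n-1} pj / (n-j+1)
// O(n^2); compiled because likelihood maximization and the coverage
// simulations evaluate it thousands of times.
// [[Rcpp::export(name = ".ld_pmf_msx")]]
NumericVector ld_pmf_msx(double m, int n_max) {
  if (m < 0 || n_max < 0) stop("m must be >= 0 and n_max >= 0");
  NumericVector p(n_max + 1);
  p[0] = std::exp(-m);
  for (int n = 1; n <= n_max; ++n) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += p[j] / (double)(n - j + 1);
    }
    p[n] = m / (double)n * acc;
  }
  return p;
}
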
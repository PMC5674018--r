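#include <Rcpp.h>
using namespace Rcpp;

// Ma-Sandri-Sarkar recursion for the Luria-Delbrueck mutant-number
// distribution: p_0 = exp(-m); p_n = (m/n) * sum_{j=0}^{n-1} p_j/(n-j+1).
// O(n_max^2), hence compiled.
// [[Rcpp::export(name = ".mss_pmf_cpp")]]
NumericVector mss_pmf_cpp(double m, int n_max) {
  if (m < 0) stop("m must be non-negative");
  if (n_max < 0) stop("n_max must be non-negative");
  NumericVector p(n_max + 1);
  p[0] = std::exp(-m);
  if (n_max == 0) return p;
  std::vector<double> inv(n_max + 2);
  for (int d = 1; d <= n_max + 1; ++d) inv[d] = 1.0 / (d + 1.0);
  for (int n = 1; n <= n_max; ++n) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += p[j] * inv[n - j];
    p[n] = m / n * s;
  }
  return p;
}
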
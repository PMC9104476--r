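#include <Rcpp.h>
using namespace Rcpp;

// Per-template counts of m-length templates within Chebyshev distance r.
// Counts include the self-match; callers subtract it where the definition
// excludes it. Templates are the first n_templates starting positions.
// [[Rcpp::export]]
IntegerVector cheb_counts_cpp(NumericVector x, int m, double r,
                              int n_templates) {
  int nt = n_templates;
  IntegerVector counts(nt);
  for (int i = 0; i < nt; ++i) counts[i] = 1;  // self
  for (int i = 0; i < nt; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool within = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { within = false; break; }
      }
      if (within) { counts[i]++; counts[j]++; }
    }
  }
  return counts;
}

// Mean normalized curve length L(k) for k = 1..k_max (Higuchi construction):
// for each offset m0 < k the decimated series x[m0], x[m0+k], ... has curve
// length sum|diff| * (n-1) / (floor((n-m0-1)/k) * k), and L(k) averages the
// offsets and divides by k once more.
// [[Rcpp::export]]
NumericVector higuchi_lengths_cpp(NumericVector x, int k_max) {
  int n = x.size();
  NumericVector lk(k_max);
  for (int k = 1; k <= k_max; ++k) {
    double acc = 0.0;
    int used = 0;
    for (int m0 = 0; m0 < k; ++m0) {
      int nm = (n - 1 - m0) / k;  // number of increments
      if (nm < 1) continue;
      double len = 0.0;
      for (int i = 1; i <= nm; ++i)
        len += std::fabs(x[m0 + i * k] - x[m0 + (i - 1) * k]);
      acc += len * (double)(n - 1) / ((double)nm * k);
      ++used;
    }
    lk[k - 1] = (acc / used) / k;
  }
  return lk;
}
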
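#include <Rcpp.h>
using namespace Rcpp;

// Raw log-odds score of every window of a coded sequence under a 4 x L
// log-odds matrix. codes: 1..4 for A,C,G,T; 0 for N (contributes 0).
// Returns a vector of length n - L + 1 (empty if the sequence is shorter
// than the motif).
// [[Rcpp::export(name = ".pwm_window_scores_cpp")]]
NumericVector pwm_window_scores_cpp(IntegerVector codes, NumericMatrix lom) {
  const int n = codes.size();
  const int L = lom.ncol();
  if (n < L) return NumericVector(0);
  const int nw = n - L + 1;
  NumericVector out(nw);
  for (int i = 0; i < nw; ++i) {
    double s = 0.0;
    for (int j = 0; j < L; ++j) {
      const int c = codes[i + j];
      if (c > 0) s += lom(c - 1, j);
    }
    out[i] = s;
  }
  return out;
}
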
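#include <Rcpp.h>
using namespace Rcpp;

// Noisy proportional-pursuit recursion for one gaze coordinate:
//   pos[t] = pos[t-1] + gain[t] * (target[t] - pos[t-1]) + noise[t]
// clipped to [0, 1]. gain varies per sample so inter-stimulus drift can be
// switched off (gain 0 outside stimulus windows).
// [[Rcpp::export(name = ".pursuit_cpp")]]
NumericVector pursuit_cpp(NumericVector target, NumericVector gain,
                          NumericVector noise, double init) {
  const int n = target.size();
  NumericVector pos(n);
  double p = init;
  for (int t = 0; t < n; ++t) {
    p = p + gain[t] * (target[t] - p) + noise[t];
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    pos[t] = p;
  }
  return pos;
}
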
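#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy with Chebyshev template distance.
//
// Templates of length m and m+1 are both taken at offsets 0..n-m-1 so every
// length-m template that is counted can also be extended by one step
// (Richman & Moorman's convention). Similarity is distance <= r, self-matches
// excluded. Returns -log(A / B) where B counts similar m-pairs and A counts
// those still similar at length m + 1; NA when either count is zero.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of extendable templates
  if (nt < 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool close_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { close_m = false; break; }
      }
      if (!close_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  if (B == 0.0 || A == 0.0) return NA_REAL;
  return -std::log(A / B);
}
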
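#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy match counts under the Chebyshev (max-norm) distance.
//
// Templates are the Nt = N - m windows x[i..i+m-1], i = 0..Nt-1, so that
// every length-m template has a length-(m+1) extension. B counts ordered
// pairs i != j whose length-m templates are within `radius` (inclusive);
// A counts those that remain within `radius` at length m+1. Self-matches
// are excluded. Counting unordered pairs and doubling is equivalent for
// the ratio A/B; we return unordered counts.
//
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double radius) {
  int n = x.size();
  int nt = n - m;
  if (nt < 2) stop("series too short for template length m");
  double a = 0.0, b = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > radius) { ok = false; break; }
      }
      if (!ok) continue;
      b += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= radius) a += 1.0;
    }
  }
  return List::create(_["a"] = a, _["b"] = b, _["n_templates"] = nt);
}

// Direct-form II transposed IIR filter with explicit initial state.
// b and a must have equal length (pad with zeros); a[0] == 1 assumed.
//
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size();
  if (a.size() != nb) stop("b and a must have equal length");
  int nz = nb - 1;
  if (zi.size() != nz) stop("zi must have length length(b) - 1");
  std::vector<double> z(zi.begin(), zi.end());
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int k = 0; k < nz - 1; ++k) {
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    }
    if (nz > 0) z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
  return y;
}
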
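#include <Rcpp.h>
using namespace Rcpp;

// Gaussian kernel sum on a uniform time grid.  Each spike contributes a
// normal density (sd = bw) scaled by its edge-correction weight.
// Contributions are truncated at +/- 8 bw, where the density has fallen to
// ~5e-15 of its peak; the truncation error is far below the numerical
// tolerances used anywhere in the package.
// [[Rcpp::export]]
NumericVector sdf_kernel_sum(NumericVector spikes, NumericVector weights,
                             double t0, double dt, int n, double bw) {
  NumericVector out(n);
  const double halfwin = 8.0 * bw;
  const double norm = 1.0 / (bw * std::sqrt(2.0 * M_PI));
  const int ns = spikes.size();
  for (int i = 0; i < ns; ++i) {
    const double s = spikes[i], w = weights[i];
    int j0 = (int)std::ceil((s - halfwin - t0) / dt);
    int j1 = (int)std::floor((s + halfwin - t0) / dt);
    if (j0 < 0) j0 = 0;
    if (j1 > n - 1) j1 = n - 1;
    for (int j = j0; j <= j1; ++j) {
      const double z = (t0 + j * dt - s) / bw;
      out[j] += w * norm * std::exp(-0.5 * z * z);
    }
  }
  return out;
}
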
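#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Literal direct-summation CWT: W(a, b) = norm_a * sum_j x[b + j] * g_a[j]
// where g_a[j] = conj(psi(j / a)) on the truncated support j = -K..K and
// norm_a folds in 1/sqrt(a) and the sampling interval. No transform tricks;
// x is treated as zero outside its own span. Intended for short inputs.
// [[Rcpp::export(name = ".cwt_oracle_cpp")]]
ComplexMatrix cwt_oracle_cpp(NumericVector x, List kernels, NumericVector norms) {
  const int n = x.size();
  const int n_scales = kernels.size();
  ComplexMatrix out(n_scales, n);
  for (int s = 0; s < n_scales; ++s) {
    ComplexVector g = kernels[s];
    const int support = g.size();          // 2K + 1 samples
    const int K = (support - 1) / 2;
    const double norm_a = norms[s];
    for (int b = 0; b < n; ++b) {
      std::complex<double> acc(0.0, 0.0);
      for (int j = -K; j <= K; ++j) {
        const int t = b + j;
        if (t < 0 || t >= n) continue;
        const Rcomplex gc = g[j + K];
        acc += x[t] * std::complex<double>(gc.r, gc.i);
      }
      out(s, b).r = norm_a * acc.real();
      out(s, b).i = norm_a * acc.imag();
    }
  }
  return out;
}
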
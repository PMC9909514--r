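// Weighted overlap-add with window-sum-squares normalization; the hot loop
// of STFT resynthesis on long recordings.
#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::NumericVector cpp_overlap_add(Rcpp::NumericMatrix framesw, int hop,
                                    int out_length,
                                    Rcpp::NumericVector w2) {
  const int n_fft = framesw.nrow(), nf = framesw.ncol();
  Rcpp::NumericVector y(out_length), wss(out_length);
  for (int f = 0; f < nf; ++f) {
    const int off = f * hop;
    const int lim = std::min(n_fft, out_length - off);
    for (int i = 0; i < lim; ++i) {
      y[off + i] += framesw(i, f);
      wss[off + i] += w2[i];
    }
  }
  for (int i = 0; i < out_length; ++i)
    if (wss[i] > 1e-10) y[i] /= wss[i];
    else y[i] = 0.0;
  return y;
}
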
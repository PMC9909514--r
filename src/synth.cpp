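// Source-filter synthesis primitives: a harmonic glottal-like source driven
// by a per-sample f0 contour, and a cascade of two-pole resonators whose
// centre frequencies vary over time (vocal-tract formant stand-in).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// f0: per-sample fundamental (Hz); harmonics up to fmax with 1/k amplitudes
// [[Rcpp::export]]
Rcpp::NumericVector cpp_harmonic_source(Rcpp::NumericVector f0, double sample_rate,
                                        double fmax) {
  const R_xlen_t n = f0.size();
  Rcpp::NumericVector out(n);
  std::vector<double> phase(n);
  double ph = 0.0;
  const double two_pi = 2.0 * M_PI;
  for (R_xlen_t i = 0; i < n; ++i) {
    ph += two_pi * f0[i] / sample_rate;
    if (ph > two_pi) ph -= two_pi;
    phase[i] = ph;
  }
  // sum_k sin(k*phase)/k for k*f0 <= fmax, via complex rotation so only one
  // sincos is evaluated per sample
  for (R_xlen_t i = 0; i < n; ++i) {
    const int kmax = std::max(1, (int)std::floor(fmax / std::max(f0[i], 1.0)));
    const double cs = std::cos(phase[i]), sn = std::sin(phase[i]);
    double zr = cs, zi = sn, acc = sn;
    for (int k = 2; k <= kmax; ++k) {
      const double nzr = zr * cs - zi * sn;
      zi = zr * sn + zi * cs;
      zr = nzr;
      acc += zi / k;
    }
    out[i] = acc;
  }
  return out;
}

// centers: n_blocks x n_formants matrix of per-block centre frequencies (Hz);
// bw: per-formant bandwidths (Hz); block_len: samples per block
// [[Rcpp::export]]
Rcpp::NumericVector cpp_tv_resonators(Rcpp::NumericVector x,
                                      Rcpp::NumericMatrix centers,
                                      Rcpp::NumericVector bw,
                                      int block_len, double sample_rate) {
  const R_xlen_t n = x.size();
  const int nf = centers.ncol();
  const int nblk = centers.nrow();
  Rcpp::NumericVector y(n);
  std::vector<double> cur(x.begin(), x.end());
  const double two_pi = 2.0 * M_PI;
  for (int f = 0; f < nf; ++f) {
    const double r = std::exp(-M_PI * bw[f] / sample_rate);
    const double g = 1.0 - r;
    double y1 = 0.0, y2 = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int blk = (int)(i / block_len);
      if (blk >= nblk) blk = nblk - 1;
      const double theta = two_pi * centers(blk, f) / sample_rate;
      const double a1 = 2.0 * r * std::cos(theta);
      const double a2 = -r * r;
      const double v = g * cur[i] + a1 * y1 + a2 * y2;
      y2 = y1;
      y1 = v;
      cur[i] = v;
    }
  }
  std::copy(cur.begin(), cur.end(), y.begin());
  return y;
}
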
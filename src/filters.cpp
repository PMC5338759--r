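#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed.
// sos: one section per row, columns b0 b1 b2 a1 a2 (a0 normalized to 1).
// [[Rcpp::export(name = ".sos_filter")]]
NumericVector sos_filter(NumericVector x, NumericMatrix sos) {
  int n = x.size(), ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 3), a2 = sos(s, 4);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Sign-preserving power-law compression, x -> sign(x) |x|^p.
// [[Rcpp::export(name = ".pow_compress")]]
NumericVector pow_compress(NumericVector x, double p) {
  int n = x.size();
  NumericVector y(n);
  bool cube = std::abs(p - (1.0 / 3.0)) < 1e-12;
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (cube)
      y[i] = std::cbrt(v);
    else
      y[i] = (v >= 0 ? 1.0 : -1.0) * std::pow(std::abs(v), p);
  }
  return y;
}

// Mean over consecutive frames of length `len`; tail samples beyond the
// last complete frame contribute a final shorter frame.
// [[Rcpp::export(name = ".frame_mean")]]
NumericVector frame_mean(NumericVector x, int len) {
  int n = x.size();
  int nf = (n + len - 1) / len;
  NumericVector y(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = f * len, i1 = std::min(n, i0 + len);
    double s = 0.0;
    for (int i = i0; i < i1; ++i) s += x[i];
    y[f] = s / (i1 - i0);
  }
  return y;
}

// Fused peripheral-model chain: for each channel, gammatone SOS cascade,
// power-law compression, hair-cell low-pass, lateral inhibition against the
// previous channel's hair-cell output (replicate padding at channel 1),
// half-wave rectification and frame averaging. Returns channels x frames.
// gt_sos: (4 * n_channels) x 5, four sections per channel.
// lpf: 1 x 5 section, or 0-row matrix to skip the low-pass.
// [[Rcpp::export(name = ".auditory_chain")]]
NumericMatrix auditory_chain(NumericVector x, NumericMatrix gt_sos,
                             NumericMatrix lpf, double p, int frame_len) {
  int n = x.size();
  int n_ch = gt_sos.nrow() / 4;
  int nf = (n + frame_len - 1) / frame_len;
  bool use_lpf = lpf.nrow() > 0;
  bool cube = std::abs(p - (1.0 / 3.0)) < 1e-12;
  NumericMatrix out(n_ch, nf);
  std::vector<double> hc(n), prev(n, 0.0);
  for (int ch = 0; ch < n_ch; ++ch) {
    // gammatone cascade into hc
    for (int i = 0; i < n; ++i) hc[i] = x[i];
    for (int s = 0; s < 4; ++s) {
      int r = ch * 4 + s;
      double b0 = gt_sos(r, 0), b1 = gt_sos(r, 1), b2 = gt_sos(r, 2);
      double a1 = gt_sos(r, 3), a2 = gt_sos(r, 4);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double xi = hc[i];
        double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        hc[i] = yi;
      }
    }
    // compression
    if (cube)
      for (int i = 0; i < n; ++i) hc[i] = std::cbrt(hc[i]);
    else
      for (int i = 0; i < n; ++i)
        hc[i] = (hc[i] >= 0 ? 1.0 : -1.0) * std::pow(std::abs(hc[i]), p);
    // hair-cell low-pass
    if (use_lpf) {
      double b0 = lpf(0, 0), b1 = lpf(0, 1), b2 = lpf(0, 2);
      double a1 = lpf(0, 3), a2 = lpf(0, 4);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double xi = hc[i];
        double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        hc[i] = yi;
      }
    }
    // lateral inhibition + rectification + frame mean
    for (int f = 0; f < nf; ++f) {
      int i0 = f * frame_len, i1 = std::min(n, i0 + frame_len);
      double s = 0.0;
      if (ch == 0) { out(ch, f) = 0.0; continue; }
      for (int i = i0; i < i1; ++i) {
        double d = hc[i] - prev[i];
        if (d > 0) s += d;
      }
      out(ch, f) = s / (i1 - i0);
    }
    std::swap(hc, prev);
  }
  return out;
}
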
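// Centroid-chord sweep over a binary region. For each angle the full line
// through the centroid is marched at sub-pixel steps with nearest-pixel
// membership; the chord is the span between the extreme in-region pixel
// centers (the caller adds the +/-0.5 px boundary offset), and the
// in-region extent (total length of in-region runs) supports the
// centroid-outside fallback.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".chord_sweep")]]
NumericMatrix chord_sweep(const LogicalMatrix& region, double cy, double cx,
                          const NumericVector& angles, double step) {
  const int H = region.nrow(), W = region.ncol();
  const double smax = std::sqrt((double)H * H + (double)W * W);
  const int ns = (int)std::ceil(smax / step);
  NumericMatrix out(angles.size(), 2);
  for (int a = 0; a < angles.size(); ++a) {
    const double ux = std::cos(angles[a]);
    const double uy = std::sin(angles[a]);
    double tmax = R_NegInf, tmin = R_PosInf;
    int n_in = 0;
    for (int i = -ns; i <= ns; ++i) {
      const double s = i * step;
      const int px = (int)std::lround(cx + s * ux);
      const int py = (int)std::lround(cy + s * uy);
      if (px < 0 || px >= W || py < 0 || py >= H) continue;
      if (!region(py, px)) continue;
      ++n_in;
      const double t = (px - cx) * ux + (py - cy) * uy;
      if (t > tmax) tmax = t;
      if (t < tmin) tmin = t;
    }
    if (n_in == 0) {
      out(a, 0) = 0.0;
      out(a, 1) = 0.0;
    } else {
      out(a, 0) = tmax - tmin + 1.0;
      out(a, 1) = n_in * step;
    }
  }
  return out;
}
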
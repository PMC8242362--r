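// anti-aliased capsule rasterization: per-pixel coverage from the exact
// distance to the centerline segment, max-blended into the image

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_draw_capsule(NumericMatrix img, double x0, double y0,
                               double x1, double y1, double w,
                               double value) {
  int nr = img.nrow(), nc = img.ncol();
  double pad = w / 2 + 1.5;
  int r0 = std::max(0, (int)std::floor(std::min(y0, y1) - pad));
  int r1 = std::min(nr - 1, (int)std::ceil(std::max(y0, y1) + pad));
  int c0 = std::max(0, (int)std::floor(std::min(x0, x1) - pad));
  int c1 = std::min(nc - 1, (int)std::ceil(std::max(x0, x1) + pad));
  double vx = x1 - x0, vy = y1 - y0;
  double l2 = vx * vx + vy * vy;
  for (int c = c0; c <= c1; ++c) {
    double px = c;
    for (int r = r0; r <= r1; ++r) {
      double py = r;
      double t = 0.0;
      if (l2 > 0) {
        t = ((px - x0) * vx + (py - y0) * vy) / l2;
        t = std::min(1.0, std::max(0.0, t));
      }
      double dx = px - (x0 + t * vx), dy = py - (y0 + t * vy);
      double d = std::sqrt(dx * dx + dy * dy);
      double cov = w / 2 + 0.5 - d;
      if (cov <= 0) continue;
      cov = std::min(1.0, cov) * value;
      if (cov > img(r, c)) img(r, c) = cov;
    }
  }
  return img;
}
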
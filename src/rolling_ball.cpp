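#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grey-scale erosion / dilation with a non-flat, ball-shaped structuring
// element: b(d) = sqrt(r^2 - d^2) - r for Euclidean offset d <= r (so the
// ball apex touches the surface from below at b(0) = 0). The background is
// the morphological opening dilate(erode(img)) with this element, i.e. the
// surface traced by the top of a ball rolled beneath the image.

static NumericMatrix ballTransform(const NumericMatrix& img, double radius,
                                   bool erode) {
  const int nr = img.nrow(), nc = img.ncol();
  const int w = (int)std::floor(radius);
  const int ww = 2 * w + 1;
  std::vector<double> prof((size_t)ww * ww);
  std::vector<bool> inside((size_t)ww * ww);
  for (int dy = -w; dy <= w; ++dy) {
    for (int dx = -w; dx <= w; ++dx) {
      double d2 = (double)dx * dx + (double)dy * dy;
      size_t idx = (size_t)(dy + w) * ww + (dx + w);
      if (d2 <= radius * radius) {
        inside[idx] = true;
        prof[idx] = std::sqrt(radius * radius - d2) - radius;
      } else {
        inside[idx] = false;
        prof[idx] = 0.0;
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int dx = -w; dx <= w; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nc) continue;
        for (int dy = -w; dy <= w; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= nr) continue;
          size_t idx = (size_t)(dy + w) * ww + (dx + w);
          if (!inside[idx]) continue;
          double v = erode ? img(yy, xx) - prof[idx] : img(yy, xx) + prof[idx];
          if (erode ? (v < best) : (v > best)) best = v;
        }
      }
      out(y, x) = best;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cppBallBackground")]]
NumericMatrix cppBallBackground(NumericMatrix img, double radius) {
  NumericMatrix er = ballTransform(img, radius, true);
  return ballTransform(er, radius, false);
}

// block minimum used when rolling the ball on a shrunken image
// [[Rcpp::export(name = ".cppBlockMin")]]
NumericMatrix cppBlockMin(NumericMatrix img, int factor) {
  const int nr = img.nrow(), nc = img.ncol();
  const int snr = (nr + factor - 1) / factor, snc = (nc + factor - 1) / factor;
  NumericMatrix out(snr, snc);
  for (int by = 0; by < snr; ++by) {
    for (int bx = 0; bx < snc; ++bx) {
      double m = R_PosInf;
      for (int y = by * factor; y < std::min(nr, (by + 1) * factor); ++y)
        for (int x = bx * factor; x < std::min(nc, (bx + 1) * factor); ++x)
          if (img(y, x) < m) m = img(y, x);
      out(by, bx) = m;
    }
  }
  return out;
}
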
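// Inverse-mapped homography warp with bilinear interpolation.
//
// Images are EBImage-style arrays: dim = (x, y) or (x, y, channels), values
// in [0, 1]. `H` is the 3x3 inverse map taking homogeneous *output* pixel
// coordinates (x, y, 1), 0-based pixel centers, to input coordinates.
// Out-of-frame samples take the background value `bg` (one value per
// channel, recycled).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".warp_cpp")]]
NumericVector warp_cpp(NumericVector img, NumericMatrix H, int out_w,
                       int out_h, NumericVector bg) {
  IntegerVector d = img.attr("dim");
  int w = d[0], h = d[1];
  int nch = d.size() >= 3 ? d[2] : 1;
  NumericVector out((size_t)out_w * out_h * nch);
  const double h11 = H(0, 0), h12 = H(0, 1), h13 = H(0, 2);
  const double h21 = H(1, 0), h22 = H(1, 1), h23 = H(1, 2);
  const double h31 = H(2, 0), h32 = H(2, 1), h33 = H(2, 2);
  for (int y = 0; y < out_h; ++y) {
    for (int x = 0; x < out_w; ++x) {
      double wz = h31 * x + h32 * y + h33;
      double xi = (h11 * x + h12 * y + h13) / wz;
      double yi = (h21 * x + h22 * y + h23) / wz;
      bool inside = xi >= 0 && xi <= w - 1 && yi >= 0 && yi <= h - 1;
      int x0 = 0, y0 = 0;
      double fx = 0, fy = 0;
      if (inside) {
        x0 = (int)std::floor(xi);
        y0 = (int)std::floor(yi);
        if (x0 >= w - 1) x0 = w - 2 >= 0 ? w - 2 : 0;
        if (y0 >= h - 1) y0 = h - 2 >= 0 ? h - 2 : 0;
        fx = xi - x0;
        fy = yi - y0;
      }
      for (int ch = 0; ch < nch; ++ch) {
        double val;
        if (!inside) {
          val = bg[ch % bg.size()];
        } else {
          size_t base = (size_t)ch * w * h;
          int x1 = x0 + 1 < w ? x0 + 1 : x0;
          int y1 = y0 + 1 < h ? y0 + 1 : y0;
          double v00 = img[base + (size_t)y0 * w + x0];
          double v10 = img[base + (size_t)y0 * w + x1];
          double v01 = img[base + (size_t)y1 * w + x0];
          double v11 = img[base + (size_t)y1 * w + x1];
          val = (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
                (1 - fx) * fy * v01 + fx * fy * v11;
        }
        out[(size_t)ch * out_w * out_h + (size_t)y * out_w + x] = val;
      }
    }
  }
  if (nch > 1)
    out.attr("dim") = IntegerVector::create(out_w, out_h, nch);
  else
    out.attr("dim") = IntegerVector::create(out_w, out_h);
  return out;
}
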
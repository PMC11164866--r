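// Scale-Invariant Feature Transform (Lowe 2004), implemented from scratch.
//
// Standard formulation: Gaussian scale-space pyramid, difference-of-Gaussian
// extrema with quadratic sub-pixel refinement, low-contrast and edge-response
// rejection, 36-bin gradient-orientation assignment and 4x4x8 descriptor
// histograms with trilinear interpolation, normalised / clipped at 0.2 /
// renormalised and quantised to 8-bit integers. Parameter names and defaults
// follow the conventional parameterisation (3 layers per octave, contrast
// threshold 0.04, edge threshold 10, base sigma 1.6, initial 2x upsampling).
//
// Images are single-channel doubles in [0, 1]; gradients and the contrast
// threshold are therefore on the unit scale rather than 0-255.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct FMat {
  int nr = 0, nc = 0;
  std::vector<float> d;
  FMat() {}
  FMat(int r, int c) : nr(r), nc(c), d((size_t)r * c, 0.f) {}
  inline float &at(int r, int c) { return d[(size_t)c * nr + r]; }
  inline float at(int r, int c) const { return d[(size_t)c * nr + r]; }
};

// reflect-101 border handling
inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

std::vector<float> gauss_kernel(double sigma) {
  int radius = (int)std::ceil(4.0 * sigma);
  if (radius < 1) radius = 1;
  std::vector<float> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    double v = std::exp(-(double)i * i / (2.0 * sigma * sigma));
    k[i + radius] = (float)v;
    s += v;
  }
  for (auto &v : k) v = (float)(v / s);
  return k;
}

FMat gauss_blur(const FMat &src, double sigma) {
  if (sigma <= 0.0) return src;
  std::vector<float> k = gauss_kernel(sigma);
  int radius = ((int)k.size() - 1) / 2;
  FMat tmp(src.nr, src.nc), out(src.nr, src.nc);
  // along rows (first index)
  for (int c = 0; c < src.nc; ++c)
    for (int r = 0; r < src.nr; ++r) {
      float acc = 0.f;
      for (int t = -radius; t <= radius; ++t)
        acc += k[t + radius] * src.at(refl(r + t, src.nr), c);
      tmp.at(r, c) = acc;
    }
  // along columns (second index)
  for (int c = 0; c < src.nc; ++c)
    for (int r = 0; r < src.nr; ++r) {
      float acc = 0.f;
      for (int t = -radius; t <= radius; ++t)
        acc += k[t + radius] * tmp.at(r, refl(c + t, src.nc));
      out.at(r, c) = acc;
    }
  return out;
}

FMat downsample2(const FMat &src) {
  FMat out(src.nr / 2, src.nc / 2);
  for (int c = 0; c < out.nc; ++c)
    for (int r = 0; r < out.nr; ++r)
      out.at(r, c) = src.at(r * 2, c * 2);
  return out;
}

FMat upsample2(const FMat &src) {
  FMat out(src.nr * 2, src.nc * 2);
  for (int c = 0; c < out.nc; ++c) {
    double yc = c * 0.5;
    int c0 = (int)yc;
    double fc = yc - c0;
    int c1 = std::min(c0 + 1, src.nc - 1);
    for (int r = 0; r < out.nr; ++r) {
      double xr = r * 0.5;
      int r0 = (int)xr;
      double fr = xr - r0;
      int r1 = std::min(r0 + 1, src.nr - 1);
      out.at(r, c) = (float)((1 - fr) * (1 - fc) * src.at(r0, c0) +
                             fr * (1 - fc) * src.at(r1, c0) +
                             (1 - fr) * fc * src.at(r0, c1) +
                             fr * fc * src.at(r1, c1));
    }
  }
  return out;
}

struct KP {
  double r, c;      // refined coords in base-image scale
  double size;      // sigma of the keypoint, base-image scale
  double angle;     // degrees in [0, 360)
  double response;
  int octave, layer;
  double scl_octv;  // sigma within its octave
  int ri, ci;       // integer coords within its octave layer
};

const int SIFT_ORI_HIST_BINS = 36;
const double SIFT_ORI_SIG_FCTR = 2.5;
const double SIFT_ORI_RADIUS = 3.0 * SIFT_ORI_SIG_FCTR;
const double SIFT_ORI_PEAK_RATIO = 0.8;
const int SIFT_DESCR_WIDTH = 4;
const int SIFT_DESCR_HIST_BINS = 8;
const double SIFT_DESCR_SCL_FCTR = 3.0;
const double SIFT_DESCR_MAG_THR = 0.2;
const double SIFT_INT_DESCR_FCTR = 512.0;

// gradient-orientation histogram around (r, c); returns max bin value
double calc_orientation_hist(const FMat &img, int r, int c, int radius,
                             double sigma, std::vector<double> &hist) {
  int n = SIFT_ORI_HIST_BINS;
  std::vector<double> raw(n, 0.0);
  double expf_scale = -1.0 / (2.0 * sigma * sigma);
  for (int i = -radius; i <= radius; ++i) {
    int y = r + i;
    if (y <= 0 || y >= img.nr - 1) continue;
    for (int j = -radius; j <= radius; ++j) {
      int x = c + j;
      if (x <= 0 || x >= img.nc - 1) continue;
      double dx = img.at(y, x + 1) - img.at(y, x - 1);
      double dy = img.at(y - 1, x) - img.at(y + 1, x);
      double w = std::exp(((double)i * i + (double)j * j) * expf_scale);
      double mag = std::sqrt(dx * dx + dy * dy);
      double ang = std::atan2(dy, dx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
      int bin = (int)std::lround(ang / 360.0 * n);
      if (bin >= n) bin -= n;
      if (bin < 0) bin += n;
      raw[bin] += w * mag;
    }
  }
  // circular smoothing with [1 4 6 4 1]/16
  double maxval = 0.0;
  for (int i = 0; i < n; ++i) {
    hist[i] = (raw[(i - 2 + n) % n] + raw[(i + 2) % n]) * (1.0 / 16.0) +
              (raw[(i - 1 + n) % n] + raw[(i + 1) % n]) * (4.0 / 16.0) +
              raw[i] * (6.0 / 16.0);
    if (hist[i] > maxval) maxval = hist[i];
  }
  return maxval;
}

bool adjust_local_extremum(const std::vector<std::vector<FMat> > &dog,
                           int o, int &l, int &r, int &c, int nlayers,
                           double contrast_thr, double edge_thr,
                           double &xr_out, double &xc_out, double &xl_out,
                           double &contr_out) {
  const int border = 5;
  double xr = 0, xc = 0, xl = 0;
  int iter = 0;
  const int max_iter = 5;
  for (; iter < max_iter; ++iter) {
    const FMat &prev = dog[o][l - 1];
    const FMat &cur = dog[o][l];
    const FMat &next = dog[o][l + 1];
    double dx = (cur.at(r, c + 1) - cur.at(r, c - 1)) * 0.5;
    double dy = (cur.at(r + 1, c) - cur.at(r - 1, c)) * 0.5;
    double ds = (next.at(r, c) - prev.at(r, c)) * 0.5;
    double v2 = cur.at(r, c) * 2.0;
    double dxx = cur.at(r, c + 1) + cur.at(r, c - 1) - v2;
    double dyy = cur.at(r + 1, c) + cur.at(r - 1, c) - v2;
    double dss = next.at(r, c) + prev.at(r, c) - v2;
    double dxy = (cur.at(r + 1, c + 1) - cur.at(r + 1, c - 1) -
                  cur.at(r - 1, c + 1) + cur.at(r - 1, c - 1)) * 0.25;
    double dxs = (next.at(r, c + 1) - next.at(r, c - 1) -
                  prev.at(r, c + 1) + prev.at(r, c - 1)) * 0.25;
    double dys = (next.at(r + 1, c) - next.at(r - 1, c) -
                  prev.at(r + 1, c) + prev.at(r - 1, c)) * 0.25;
    // solve H * X = -g (3x3, Cramer)
    double H[3][3] = {{dxx, dxy, dxs}, {dxy, dyy, dys}, {dxs, dys, dss}};
    double g[3] = {dx, dy, ds};
    double det = H[0][0] * (H[1][1] * H[2][2] - H[1][2] * H[2][1]) -
                 H[0][1] * (H[1][0] * H[2][2] - H[1][2] * H[2][0]) +
                 H[0][2] * (H[1][0] * H[2][1] - H[1][1] * H[2][0]);
    if (std::fabs(det) < 1e-20) return false;
    double X[3];
    for (int k = 0; k < 3; ++k) {
      double Hk[3][3];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) Hk[a][b] = H[a][b];
      for (int a = 0; a < 3; ++a) Hk[a][k] = -g[a];
      X[k] = (Hk[0][0] * (Hk[1][1] * Hk[2][2] - Hk[1][2] * Hk[2][1]) -
              Hk[0][1] * (Hk[1][0] * Hk[2][2] - Hk[1][2] * Hk[2][0]) +
              Hk[0][2] * (Hk[1][0] * Hk[2][1] - Hk[1][1] * Hk[2][0])) / det;
    }
    xc = X[0]; xr = X[1]; xl = X[2];
    if (std::fabs(xc) < 0.5 && std::fabs(xr) < 0.5 && std::fabs(xl) < 0.5)
      break;
    if (std::fabs(xc) > 1e6 || std::fabs(xr) > 1e6 || std::fabs(xl) > 1e6)
      return false;
    c += (int)std::lround(xc);
    r += (int)std::lround(xr);
    l += (int)std::lround(xl);
    if (l < 1 || l > nlayers || c < border || c >= cur.nc - border ||
        r < border || r >= cur.nr - border)
      return false;
  }
  if (iter >= max_iter) return false;
  const FMat &prev = dog[o][l - 1];
  const FMat &cur = dog[o][l];
  const FMat &next = dog[o][l + 1];
  double dx = (cur.at(r, c + 1) - cur.at(r, c - 1)) * 0.5;
  double dy = (cur.at(r + 1, c) - cur.at(r - 1, c)) * 0.5;
  double ds = (next.at(r, c) - prev.at(r, c)) * 0.5;
  double contr = cur.at(r, c) + 0.5 * (dx * xc + dy * xr + ds * xl);
  if (std::fabs(contr) * nlayers < contrast_thr) return false;
  double v2 = cur.at(r, c) * 2.0;
  double dxx = cur.at(r, c + 1) + cur.at(r, c - 1) - v2;
  double dyy = cur.at(r + 1, c) + cur.at(r - 1, c) - v2;
  double dxy = (cur.at(r + 1, c + 1) - cur.at(r + 1, c - 1) -
                cur.at(r - 1, c + 1) + cur.at(r - 1, c - 1)) * 0.25;
  double tr = dxx + dyy;
  double det2 = dxx * dyy - dxy * dxy;
  if (det2 <= 0 || tr * tr * edge_thr >= (edge_thr + 1) * (edge_thr + 1) * det2)
    return false;
  xr_out = xr; xc_out = xc; xl_out = xl; contr_out = contr;
  return true;
}

void calc_descriptor(const FMat &img, double ptr, double ptc, double ori,
                     double scl, unsigned char *dst) {
  const int d = SIFT_DESCR_WIDTH, n = SIFT_DESCR_HIST_BINS;
  int ptr_i = (int)std::lround(ptr);
  int ptc_i = (int)std::lround(ptc);
  double roff = ptr_i - ptr;  // sub-pixel offset of the sampling grid
  double coff = ptc_i - ptc;
  double cos_t = std::cos(ori * M_PI / 180.0);
  double sin_t = std::sin(ori * M_PI / 180.0);
  double bins_per_rad = n / 360.0;
  double exp_scale = -1.0 / (d * d * 0.5);
  double hist_width = SIFT_DESCR_SCL_FCTR * scl;
  int radius = (int)std::lround(hist_width * std::sqrt(2.0) * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)img.nr * img.nr +
                                           (double)img.nc * img.nc));
  cos_t /= hist_width;
  sin_t /= hist_width;
  std::vector<double> hist((d + 2) * (d + 2) * (n + 2), 0.0);
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      // offsets relative to the exact (sub-pixel) keypoint position
      double jj = j + coff, ii = i + roff;
      double c_rot = jj * cos_t - ii * sin_t;
      double r_rot = jj * sin_t + ii * cos_t;
      double rbin = r_rot + d / 2 - 0.5;
      double cbin = c_rot + d / 2 - 0.5;
      int r = ptr_i + i, c = ptc_i + j;
      if (rbin > -1 && rbin < d && cbin > -1 && cbin < d &&
          r > 0 && r < img.nr - 1 && c > 0 && c < img.nc - 1) {
        double dx = img.at(r, c + 1) - img.at(r, c - 1);
        double dy = img.at(r - 1, c) - img.at(r + 1, c);
        double ang = std::atan2(dy, dx) * 180.0 / M_PI;
        if (ang < 0) ang += 360.0;
        double obin = (ang - ori) * bins_per_rad;
        double mag = std::sqrt(dx * dx + dy * dy) *
                     std::exp((c_rot * c_rot + r_rot * r_rot) * exp_scale);
        int r0 = (int)std::floor(rbin);
        int c0 = (int)std::floor(cbin);
        int o0 = (int)std::floor(obin);
        rbin -= r0; cbin -= c0; obin -= o0;
        if (o0 < 0) o0 += n;
        if (o0 >= n) o0 -= n;
        double v_r1 = mag * rbin, v_r0 = mag - v_r1;
        double v_rc11 = v_r1 * cbin, v_rc10 = v_r1 - v_rc11;
        double v_rc01 = v_r0 * cbin, v_rc00 = v_r0 - v_rc01;
        double v_rco111 = v_rc11 * obin, v_rco110 = v_rc11 - v_rco111;
        double v_rco101 = v_rc10 * obin, v_rco100 = v_rc10 - v_rco101;
        double v_rco011 = v_rc01 * obin, v_rco010 = v_rc01 - v_rco011;
        double v_rco001 = v_rc00 * obin, v_rco000 = v_rc00 - v_rco001;
        size_t idx = ((r0 + 1) * (d + 2) + (c0 + 1)) * (n + 2) + o0;
        hist[idx] += v_rco000;
        hist[idx + 1] += v_rco001;
        hist[idx + (n + 2)] += v_rco010;
        hist[idx + (n + 3)] += v_rco011;
        hist[idx + (d + 2) * (n + 2)] += v_rco100;
        hist[idx + (d + 2) * (n + 2) + 1] += v_rco101;
        hist[idx + (d + 3) * (n + 2)] += v_rco110;
        hist[idx + (d + 3) * (n + 2) + 1] += v_rco111;
      }
    }
  }
  std::vector<double> dstf(d * d * n, 0.0);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      size_t idx = ((i + 1) * (d + 2) + (j + 1)) * (n + 2);
      hist[idx] += hist[idx + n];
      hist[idx + 1] += hist[idx + n + 1];
      for (int k = 0; k < n; ++k) dstf[(i * d + j) * n + k] = hist[idx + k];
    }
  double nrm2 = 0.0;
  for (auto v : dstf) nrm2 += v * v;
  double thr = std::sqrt(nrm2) * SIFT_DESCR_MAG_THR;
  nrm2 = 0.0;
  for (auto &v : dstf) {
    if (v > thr) v = thr;
    nrm2 += v * v;
  }
  double factor = SIFT_INT_DESCR_FCTR / std::max(std::sqrt(nrm2), 1e-12);
  for (int k = 0; k < d * d * n; ++k) {
    double v = dstf[k] * factor;
    dst[k] = (unsigned char)std::min(255.0, std::max(0.0, std::lround(v) * 1.0));
  }
}

}  // namespace

// [[Rcpp::export(name = ".sift_cpp")]]
List sift_cpp(NumericMatrix image, int n_octave_layers = 3,
              double contrast_threshold = 0.04, double edge_threshold = 10.0,
              double sigma = 1.6, bool upscale = true, int max_features = 0) {
  int nr = image.nrow(), nc = image.ncol();
  if (std::min(nr, nc) < 16)
    stop("image too small for SIFT scale-space pyramid (min side 16 px)");
  FMat base0(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) base0.at(r, c) = (float)image(r, c);
  FMat base;
  double init_blur = 0.5;  // assumed blur of the input image
  if (upscale) {
    base = upsample2(base0);
    double sd = std::sqrt(std::max(sigma * sigma - 4.0 * init_blur * init_blur,
                                   0.01));
    base = gauss_blur(base, sd);
  } else {
    double sd = std::sqrt(std::max(sigma * sigma - init_blur * init_blur,
                                   0.01));
    base = gauss_blur(base0, sd);
  }
  int n_octaves = (int)std::lround(
      std::log((double)std::min(base.nr, base.nc)) / std::log(2.0) - 2.0);
  if (n_octaves < 1) n_octaves = 1;

  int nlayers = n_octave_layers;
  std::vector<double> sig(nlayers + 3);
  sig[0] = sigma;
  double k2 = std::pow(2.0, 1.0 / nlayers);
  for (int i = 1; i < nlayers + 3; ++i) {
    double sig_prev = sigma * std::pow(k2, i - 1);
    double sig_total = sig_prev * k2;
    sig[i] = std::sqrt(sig_total * sig_total - sig_prev * sig_prev);
  }
  std::vector<std::vector<FMat> > gauss(n_octaves), dog(n_octaves);
  for (int o = 0; o < n_octaves; ++o) {
    gauss[o].resize(nlayers + 3);
    for (int i = 0; i < nlayers + 3; ++i) {
      if (i == 0) {
        gauss[o][i] = (o == 0) ? base : downsample2(gauss[o - 1][nlayers]);
      } else {
        gauss[o][i] = gauss_blur(gauss[o][i - 1], sig[i]);
      }
    }
    dog[o].resize(nlayers + 2);
    for (int i = 0; i < nlayers + 2; ++i) {
      const FMat &a = gauss[o][i], &b = gauss[o][i + 1];
      FMat dd(a.nr, a.nc);
      for (size_t t = 0; t < dd.d.size(); ++t) dd.d[t] = b.d[t] - a.d[t];
      dog[o][i] = dd;
    }
  }

  const int border = 5;
  double prelim_thr = 0.5 * contrast_threshold / nlayers;
  std::vector<KP> kps;
  for (int o = 0; o < n_octaves; ++o) {
    for (int l = 1; l <= nlayers; ++l) {
      const FMat &prev = dog[o][l - 1];
      const FMat &cur = dog[o][l];
      const FMat &next = dog[o][l + 1];
      if (cur.nr < 2 * border + 2 || cur.nc < 2 * border + 2) continue;
      for (int c = border; c < cur.nc - border; ++c) {
        for (int r = border; r < cur.nr - border; ++r) {
          float v = cur.at(r, c);
          if (std::fabs(v) <= prelim_thr) continue;
          bool is_max = true, is_min = true;
          for (int dl = -1; dl <= 1 && (is_max || is_min); ++dl) {
            const FMat &lay = dl == -1 ? prev : (dl == 0 ? cur : next);
            for (int dc = -1; dc <= 1; ++dc)
              for (int dr = -1; dr <= 1; ++dr) {
                if (dl == 0 && dc == 0 && dr == 0) continue;
                float nv = lay.at(r + dr, c + dc);
                if (nv > v) is_max = false;
                if (nv < v) is_min = false;
              }
          }
          if (!is_max && !is_min) continue;
          int rl = l, rr = r, rc = c;
          double xr, xc, xl, contr;
          if (!adjust_local_extremum(dog, o, rl, rr, rc, nlayers,
                                     contrast_threshold, edge_threshold,
                                     xr, xc, xl, contr))
            continue;
          KP kp;
          double scale_mult = std::pow(2.0, o);
          kp.r = (rr + xr) * scale_mult;
          kp.c = (rc + xc) * scale_mult;
          kp.scl_octv = sigma * std::pow(2.0, (rl + xl) / nlayers);
          kp.size = kp.scl_octv * scale_mult;
          kp.response = std::fabs(contr);
          kp.octave = o;
          kp.layer = rl;
          kp.ri = rr;
          kp.ci = rc;
          // orientation assignment
          const FMat &gimg = gauss[o][rl];
          int radius = (int)std::lround(SIFT_ORI_RADIUS * kp.scl_octv);
          std::vector<double> hist(SIFT_ORI_HIST_BINS);
          double omax = calc_orientation_hist(
              gimg, rr, rc, radius, SIFT_ORI_SIG_FCTR * kp.scl_octv, hist);
          double mag_thr = omax * SIFT_ORI_PEAK_RATIO;
          int n = SIFT_ORI_HIST_BINS;
          for (int b = 0; b < n; ++b) {
            int bl = (b - 1 + n) % n, br = (b + 1) % n;
            if (hist[b] > hist[bl] && hist[b] > hist[br] &&
                hist[b] >= mag_thr) {
              double bin = b + 0.5 * (hist[bl] - hist[br]) /
                                   (hist[bl] - 2 * hist[b] + hist[br]);
              if (bin < 0) bin += n;
              if (bin >= n) bin -= n;
              KP kp2 = kp;
              kp2.angle = bin * (360.0 / n);
              kps.push_back(kp2);
            }
          }
        }
      }
    }
  }

  if (max_features > 0 && (int)kps.size() > max_features) {
    std::stable_sort(kps.begin(), kps.end(),
                     [](const KP &a, const KP &b) {
                       return a.response > b.response;
                     });
    kps.resize(max_features);
  }

  int nkp = (int)kps.size();
  NumericMatrix kpmat(nkp, 6);
  IntegerMatrix desc(nkp, 128);
  std::vector<unsigned char> buf(128);
  double coord_scale = upscale ? 0.5 : 1.0;
  for (int i = 0; i < nkp; ++i) {
    const KP &kp = kps[i];
    const FMat &gimg = gauss[kp.octave][kp.layer];
    double scale_mult = std::pow(2.0, kp.octave);
    calc_descriptor(gimg, kp.r / scale_mult, kp.c / scale_mult, kp.angle,
                    kp.scl_octv, buf.data());
    for (int j = 0; j < 128; ++j) desc(i, j) = buf[j];
    kpmat(i, 0) = kp.r * coord_scale;       // row in the input image (0-based)
    kpmat(i, 1) = kp.c * coord_scale;       // col in the input image (0-based)
    kpmat(i, 2) = kp.size * coord_scale;    // keypoint sigma, input px
    kpmat(i, 3) = kp.angle;                 // degrees
    kpmat(i, 4) = kp.response;
    kpmat(i, 5) = kp.octave;
  }
  colnames(kpmat) = CharacterVector::create("row", "col", "scale", "angle",
                                            "response", "octave");
  return List::create(_["keypoints"] = kpmat, _["descriptors"] = desc);
}
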
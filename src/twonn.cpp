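// Exact two-nearest-neighbour search between two descriptor sets, both
// directions in one pass over the pairwise L2 distances. This is the hot
// loop of database matching: the ratio test needs (d1, d2) per query
// feature, and symmetry checking needs the same in the reverse direction.
// Ties keep the lowest index (strict < comparisons).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".two_nn_both_cpp")]]
List two_nn_both_cpp(IntegerMatrix A, IntegerMatrix B) {
  int n = A.nrow(), m = B.nrow(), p = A.ncol();
  // row-major float copies for contiguous inner products
  std::vector<float> a((size_t)n * p), b((size_t)m * p);
  std::vector<float> na(n), nb(m);
  for (int i = 0; i < n; ++i) {
    float s = 0.f;
    for (int k = 0; k < p; ++k) {
      float v = (float)A(i, k);
      a[(size_t)i * p + k] = v;
      s += v * v;
    }
    na[i] = s;
  }
  for (int j = 0; j < m; ++j) {
    float s = 0.f;
    for (int k = 0; k < p; ++k) {
      float v = (float)B(j, k);
      b[(size_t)j * p + k] = v;
      s += v * v;
    }
    nb[j] = s;
  }
  std::vector<double> fd1(n, R_PosInf), fd2(n, R_PosInf);
  std::vector<int> fj1(n, -1), fj2(n, -1);
  std::vector<double> rd1(m, R_PosInf), rd2(m, R_PosInf);
  std::vector<int> rj1(m, -1), rj2(m, -1);
  for (int i = 0; i < n; ++i) {
    const float *ai = &a[(size_t)i * p];
    for (int j = 0; j < m; ++j) {
      const float *bj = &b[(size_t)j * p];
      float dot = 0.f;
      for (int k = 0; k < p; ++k) dot += ai[k] * bj[k];
      float d2f = na[i] + nb[j] - 2.f * dot;
      double d2 = d2f > 0.f ? (double)d2f : 0.0;
      if (d2 < fd1[i]) {
        fd2[i] = fd1[i]; fj2[i] = fj1[i];
        fd1[i] = d2; fj1[i] = j;
      } else if (d2 < fd2[i]) {
        fd2[i] = d2; fj2[i] = j;
      }
      if (d2 < rd1[j]) {
        rd2[j] = rd1[j]; rj2[j] = rj1[j];
        rd1[j] = d2; rj1[j] = i;
      } else if (d2 < rd2[j]) {
        rd2[j] = d2; rj2[j] = i;
      }
    }
  }
  auto finish = [](std::vector<double> &v) {
    for (auto &x : v)
      if (R_finite(x)) x = std::sqrt(x);
  };
  finish(fd1); finish(fd2); finish(rd1); finish(rd2);
  return List::create(
      _["f_j1"] = IntegerVector(fj1.begin(), fj1.end()),
      _["f_d1"] = NumericVector(fd1.begin(), fd1.end()),
      _["f_d2"] = NumericVector(fd2.begin(), fd2.end()),
      _["r_j1"] = IntegerVector(rj1.begin(), rj1.end()),
      _["r_d1"] = NumericVector(rd1.begin(), rd1.end()),
      _["r_d2"] = NumericVector(rd2.begin(), rd2.end()));
}
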
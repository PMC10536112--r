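#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur with replicate edge padding.
// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(H, W), out(H, W);
  // along rows (vertical)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(H - 1, std::max(0, i + t));
        acc += k[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // along columns (horizontal)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(W - 1, std::max(0, j + t));
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// 3x3 median filter, replicate edge padding.
// [[Rcpp::export(name = ".cpp_median3")]]
NumericMatrix cpp_median3(const NumericMatrix& img) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  double v[9];
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int n = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(H - 1, std::max(0, i + di));
          int jj = std::min(W - 1, std::max(0, j + dj));
          v[n++] = img(ii, jj);
        }
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  return out;
}

// Inverse rigid/affine warp. For every destination pixel (i,j) (0-based,
// row/col) the source location is
//   src_row = a11*i + a12*j + t1,  src_col = a21*i + a22*j + t2
// Bilinear (bilinear=true) or nearest-neighbour sampling; samples falling
// outside the source raster produce fill and valid = 0.
// [[Rcpp::export(name = ".cpp_warp")]]
List cpp_warp(const NumericMatrix& img, const NumericVector& par,
              int Hout, int Wout, bool bilinear, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const double a11 = par[0], a12 = par[1], t1 = par[2];
  const double a21 = par[3], a22 = par[4], t2 = par[5];
  NumericMatrix out(Hout, Wout);
  IntegerMatrix valid(Hout, Wout);
  for (int j = 0; j < Wout; ++j)
    for (int i = 0; i < Hout; ++i) {
      double si = a11 * i + a12 * j + t1;
      double sj = a21 * i + a22 * j + t2;
      if (bilinear) {
        if (si < 0 || sj < 0 || si > H - 1 || sj > W - 1) {
          out(i, j) = fill;
        } else {
          int i0 = (int)std::floor(si), j0 = (int)std::floor(sj);
          int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
          double fi = si - i0, fj = sj - j0;
          out(i, j) = (1 - fi) * (1 - fj) * img(i0, j0) +
                      fi * (1 - fj) * img(i1, j0) +
                      (1 - fi) * fj * img(i0, j1) +
                      fi * fj * img(i1, j1);
          valid(i, j) = 1;
        }
      } else {
        int ii = (int)std::lround(si), jj = (int)std::lround(sj);
        if (ii < 0 || jj < 0 || ii > H - 1 || jj > W - 1) {
          out(i, j) = fill;
        } else {
          out(i, j) = img(ii, jj);
          valid(i, j) = 1;
        }
      }
    }
  return List::create(_["image"] = out, _["valid"] = valid);
}

// Stamp soft discs of radius r at the given (row, col) centres; returns the
// max-combined coverage map in [0,1] (soft edge of ~1 px). Used by the
// phantom generator to rasterize vessel centrelines.
// [[Rcpp::export(name = ".cpp_stamp_discs")]]
NumericMatrix cpp_stamp_discs(int H, int W, const NumericVector& ci,
                              const NumericVector& cj, double r) {
  NumericMatrix out(H, W);
  const int n = ci.size();
  const int R = (int)std::ceil(r + 1.0);
  for (int p = 0; p < n; ++p) {
    const double y = ci[p], x = cj[p];
    const int i0 = std::max(0, (int)std::floor(y) - R);
    const int i1 = std::min(H - 1, (int)std::ceil(y) + R);
    const int j0 = std::max(0, (int)std::floor(x) - R);
    const int j1 = std::min(W - 1, (int)std::ceil(x) + R);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double d = std::sqrt((i - y) * (i - y) + (j - x) * (j - x));
        double a = std::min(1.0, std::max(0.0, r + 0.5 - d));
        if (a > out(i, j)) out(i, j) = a;
      }
  }
  return out;
}
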
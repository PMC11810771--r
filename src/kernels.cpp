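#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Scalar (unthreaded) cores for the three shipped kernels. All operate on
// replicate-padded inputs where possible so that the same core serves both the
// whole-image call and the row-chunked parallel strategy: replicate padding of
// the full image is exactly equivalent to clamping reads at the image border.

// 2D cross-correlation on a replicate-padded image.
// P is (H + K - 1) x (W + K - 1); out(i,j) = sum_{u,v} kern(u,v) * P(i+u, j+v),
// which equals the edge-clamped sum over the original image.
// [[Rcpp::export]]
NumericMatrix conv2d_padded_cpp(NumericMatrix P, NumericMatrix kern) {
  const int K = kern.nrow();
  const int H = P.nrow() - (K - 1);
  const int W = P.ncol() - (K - 1);
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int u = 0; u < K; ++u)
        for (int v = 0; v < K; ++v)
          acc += kern(u, v) * P(i + u, j + v);
      out(i, j) = acc;
    }
  }
  return out;
}

static inline double cr_weight(double t) {
  t = std::fabs(t);
  if (t <= 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t <= 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// Catmull-Rom upsampling of one frame, output rows [row0, row1] (0-based,
// inclusive) of the mag-times enlarged frame. Output coordinate (i, j) samples
// input position (i / mag, j / mag); the 4x4 tap neighbourhood is edge-clamped.
// [[Rcpp::export]]
NumericMatrix cr_zoom_rows_cpp(NumericMatrix F, int mag, int row0, int row1) {
  const int H = F.nrow(), W = F.ncol();
  const int OW = W * mag;
  const int nr = row1 - row0 + 1;
  NumericMatrix out(nr, OW);

  // Column weights/taps are shared by every output row: precompute.
  std::vector<double> wx(4 * OW);
  std::vector<int> ix(4 * OW);
  for (int j = 0; j < OW; ++j) {
    double x = static_cast<double>(j) / mag;
    int bx = static_cast<int>(std::floor(x));
    for (int n = 0; n < 4; ++n) {
      int t = bx - 1 + n;
      wx[4 * j + n] = cr_weight(x - t);
      ix[4 * j + n] = std::min(std::max(t, 0), W - 1);
    }
  }

  for (int i = row0; i <= row1; ++i) {
    double y = static_cast<double>(i) / mag;
    int by = static_cast<int>(std::floor(y));
    double wy[4];
    int iy[4];
    for (int m = 0; m < 4; ++m) {
      int t = by - 1 + m;
      wy[m] = cr_weight(y - t);
      iy[m] = std::min(std::max(t, 0), H - 1);
    }
    for (int j = 0; j < OW; ++j) {
      double acc = 0.0;
      for (int m = 0; m < 4; ++m) {
        double row = 0.0;
        for (int n = 0; n < 4; ++n)
          row += wx[4 * j + n] * F(iy[m], ix[4 * j + n]);
        acc += wy[m] * row;
      }
      out(i - row0, j) = acc;
    }
  }
  return out;
}

// Nonlocal-means on a replicate-padded image.
// P is (H + 2*halo) x (W + 2*halo) with halo = d + pr (search radius d, patch
// radius pr). For each of the H x W output pixels the weight against the
// neighbour at offset (dy, dx), |dy|,|dx| <= d, is
//   w = exp(-max(d2 - 2*sigma^2, 0) / h^2),
// d2 the mean squared difference between the edge-clamped patches, and the
// output is the w-weighted average of the (clamped) neighbour intensities.
// [[Rcpp::export]]
NumericMatrix nlm_padded_cpp(NumericMatrix P, int H, int W, int d, int pr,
                             double sigma, double h) {
  const int halo = d + pr;
  NumericMatrix out(H, W);
  const double two_sigma2 = 2.0 * sigma * sigma;
  const double h2 = h * h;
  const double pn = static_cast<double>((2 * pr + 1) * (2 * pr + 1));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int ci = i + halo, cj = j + halo;
      double wsum = 0.0, vsum = 0.0;
      for (int dx = -d; dx <= d; ++dx) {
        for (int dy = -d; dy <= d; ++dy) {
          double ss = 0.0;
          for (int px = -pr; px <= pr; ++px)
            for (int py = -pr; py <= pr; ++py) {
              double diff = P(ci + py, cj + px) - P(ci + dy + py, cj + dx + px);
              ss += diff * diff;
            }
          double e = ss / pn - two_sigma2;
          if (e < 0.0) e = 0.0;
          double w = std::exp(-e / h2);
          wsum += w;
          vsum += w * P(ci + dy, cj + dx);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}
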
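// Compiled kernels for the pixel-heavy inner loops: bilinear rotation,
// summed-area tables, and per-box mean-pooled grid features. Semantics
// mirror the documented R-level contracts exactly (same rounding as R's
// round(), same half-open box convention).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotate an h x w x 3 image about its center by angle degrees (positive =
// counterclockwise on screen, y down), bilinear resampling, `fill` outside.
// [[Rcpp::export]]
NumericVector cpp_rotate_bilinear(NumericVector img, double angle_deg,
                                  NumericVector fill) {
  IntegerVector dims = img.attr("dim");
  int h = dims[0], w = dims[1];
  NumericVector out(img.size());
  out.attr("dim") = dims;
  double th = -angle_deg * M_PI / 180.0; // inverse map
  double c = std::cos(th), s = std::sin(th);
  double cx = w / 2.0, cy = h / 2.0;
  int plane = h * w;
  for (int x = 0; x < w; ++x) {
    double xo = x + 0.5 - cx;
    for (int y = 0; y < h; ++y) {
      double yo = y + 0.5 - cy;
      // forward rotation matrix [c, s; -s, c] applied with inverse angle
      double sx = cx + c * xo + s * yo - 0.5;
      double sy = cy - s * xo + c * yo - 0.5;
      double x0 = std::floor(sx), y0 = std::floor(sy);
      double fx = sx - x0, fy = sy - y0;
      int out_idx = y + h * x;
      for (int ch = 0; ch < 3; ++ch) {
        double v[4];
        int dx[2] = {(int)x0, (int)x0 + 1}, dy[2] = {(int)y0, (int)y0 + 1};
        for (int j = 0; j < 2; ++j) {
          for (int i = 0; i < 2; ++i) {
            int xx = dx[i], yy = dy[j];
            if (xx < 0 || xx >= w || yy < 0 || yy >= h) {
              v[2 * j + i] = fill[ch];
            } else {
              v[2 * j + i] = img[yy + h * xx + plane * ch];
            }
          }
        }
        out[out_idx + plane * ch] =
          (1 - fy) * ((1 - fx) * v[0] + fx * v[1]) +
          fy * ((1 - fx) * v[2] + fx * v[3]);
      }
    }
  }
  return out;
}

// Summed-area table per channel: S[i+1, j+1, ch] = sum img[1..i, 1..j, ch].
// [[Rcpp::export]]
NumericVector cpp_integral(NumericVector img) {
  IntegerVector dims = img.attr("dim");
  int h = dims[0], w = dims[1];
  int H = h + 1, W = w + 1;
  NumericVector out(H * W * 3);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  for (int ch = 0; ch < 3; ++ch) {
    int po = H * W * ch, pi = h * w * ch;
    for (int x = 1; x < W; ++x) {
      double colsum = 0.0;
      for (int y = 1; y < H; ++y) {
        colsum += img[pi + (y - 1) + h * (x - 1)];
        out[po + y + H * x] = out[po + y + H * (x - 1)] + colsum;
      }
    }
  }
  return out;
}

// Mean-pooled gr x gc grid features for n boxes from a summed-area table.
// Cell edges are rounded with R's round() semantics; each feature is
// (cell mean - channel_mean) * scale; the last column is an intercept.
// [[Rcpp::export]]
NumericMatrix cpp_pool_features(NumericVector S, NumericMatrix boxes,
                                int gr, int gc, NumericVector channel_means,
                                double scale) {
  IntegerVector dims = S.attr("dim");
  int H = dims[0], W = dims[1];
  int h = H - 1, w = W - 1;
  int n = boxes.nrow();
  int d = 3 * gr * gc;
  NumericMatrix out(n, d + 1);
  for (int b = 0; b < n; ++b) {
    double x1 = std::min(std::max(boxes(b, 0), 0.0), (double)w);
    double y1 = std::min(std::max(boxes(b, 1), 0.0), (double)h);
    double x2 = std::min(std::max(boxes(b, 2), 0.0), (double)w);
    double y2 = std::min(std::max(boxes(b, 3), 0.0), (double)h);
    int col = 0;
    for (int i = 0; i < gr; ++i) {
      int ya = (int)R::fround(y1 + i * (y2 - y1) / gr, 0);
      int yb = (int)R::fround(y1 + (i + 1) * (y2 - y1) / gr, 0);
      int ymin = std::min(ya + 1, h);
      if (yb < ymin) yb = ymin;
      for (int j = 0; j < gc; ++j) {
        int xa = (int)R::fround(x1 + j * (x2 - x1) / gc, 0);
        int xb = (int)R::fround(x1 + (j + 1) * (x2 - x1) / gc, 0);
        int xmin = std::min(xa + 1, w);
        if (xb < xmin) xb = xmin;
        double area = (double)(yb - ya) * (xb - xa);
        if (area < 1) area = 1;
        for (int ch = 0; ch < 3; ++ch) {
          int po = H * W * ch;
          double cell = S[po + yb + H * xb] - S[po + ya + H * xb] -
            S[po + yb + H * xa] + S[po + ya + H * xa];
          out(b, col + ch) = (cell / area - channel_means[ch]) * scale;
        }
        col += 3;
      }
    }
    out(b, d) = 1.0;
  }
  return out;
}

// Fused rotate-then-crop: returns the cs x cs window with top-left (ox, oy)
// of the image rotated about its center, sampling the source directly.
// Bitwise-identical to cpp_rotate_bilinear followed by window selection.
// [[Rcpp::export]]
NumericVector cpp_rotate_crop(NumericVector img, double angle_deg,
                              NumericVector fill, int ox, int oy, int cs) {
  IntegerVector dims = img.attr("dim");
  int h = dims[0], w = dims[1];
  NumericVector out(cs * cs * 3);
  out.attr("dim") = IntegerVector::create(cs, cs, 3);
  double th = -angle_deg * M_PI / 180.0;
  double c = std::cos(th), s = std::sin(th);
  double cx = w / 2.0, cy = h / 2.0;
  int plane = h * w, oplane = cs * cs;
  for (int x = 0; x < cs; ++x) {
    double xo = x + ox + 0.5 - cx;
    for (int y = 0; y < cs; ++y) {
      double yo = y + oy + 0.5 - cy;
      double sx = cx + c * xo + s * yo - 0.5;
      double sy = cy - s * xo + c * yo - 0.5;
      double x0 = std::floor(sx), y0 = std::floor(sy);
      double fx = sx - x0, fy = sy - y0;
      int out_idx = y + cs * x;
      for (int ch = 0; ch < 3; ++ch) {
        double v[4];
        int dx[2] = {(int)x0, (int)x0 + 1}, dy[2] = {(int)y0, (int)y0 + 1};
        for (int j = 0; j < 2; ++j) {
          for (int i = 0; i < 2; ++i) {
            int xx = dx[i], yy = dy[j];
            if (xx < 0 || xx >= w || yy < 0 || yy >= h) {
              v[2 * j + i] = fill[ch];
            } else {
              v[2 * j + i] = img[yy + h * xx + plane * ch];
            }
          }
        }
        out[out_idx + oplane * ch] =
          (1 - fy) * ((1 - fx) * v[0] + fx * v[1]) +
          fy * ((1 - fx) * v[2] + fx * v[3]);
      }
    }
  }
  return out;
}

// Pairwise IoU between two box sets (half-open boxes, columns
// x_min, y_min, x_max, y_max).
// [[Rcpp::export]]
NumericMatrix cpp_iou_matrix(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  NumericMatrix out(n, m);
  std::vector<double> area_b(m);
  for (int j = 0; j < m; ++j) {
    area_b[j] = (b(j, 2) - b(j, 0)) * (b(j, 3) - b(j, 1));
  }
  for (int i = 0; i < n; ++i) {
    double ax1 = a(i, 0), ay1 = a(i, 1), ax2 = a(i, 2), ay2 = a(i, 3);
    double area_a = (ax2 - ax1) * (ay2 - ay1);
    for (int j = 0; j < m; ++j) {
      double iw = std::min(ax2, b(j, 2)) - std::max(ax1, b(j, 0));
      if (iw <= 0) continue;
      double ih = std::min(ay2, b(j, 3)) - std::max(ay1, b(j, 1));
      if (ih <= 0) continue;
      double inter = iw * ih;
      double uni = area_a + area_b[j] - inter;
      out(i, j) = uni > 0 ? inter / uni : 0.0;
    }
  }
  return out;
}
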
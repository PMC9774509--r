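// Image primitives shared by the synthetic renderer, the augmentation
// operators and Grad-CAM upsampling. Images are (H, W, C) arrays in [0,1].
#include <Rcpp.h>
using namespace Rcpp;

static inline double sample_bilinear(const double* img, int H, int W,
                                     double y, double x) {
  // edge-replicate outside the frame
  if (y < 0) y = 0; if (y > H - 1) y = H - 1;
  if (x < 0) x = 0; if (x > W - 1) x = W - 1;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
  double fy = y - y0, fx = x - x0;
  double v00 = img[y0 + H * x0], v01 = img[y0 + H * x1];
  double v10 = img[y1 + H * x0], v11 = img[y1 + H * x1];
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// Affine warp: output pixel (r, c) sampled at input (a11*r + a12*c + t1,
// a21*r + a22*c + t2), coordinates measured from the image centre.
// [[Rcpp::export]]
NumericVector warp_affine_cpp(NumericVector img, NumericVector A,
                              NumericVector t) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out(Dimension(H, W, C));
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int ch = 0; ch < C; ++ch) {
    const double* src = img.begin() + (size_t)H * W * ch;
    double* dst = out.begin() + (size_t)H * W * ch;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        double ry = r - cy, rx = c - cx;
        double sy = A[0] * ry + A[2] * rx + t[0] + cy;
        double sx = A[1] * ry + A[3] * rx + t[1] + cx;
        dst[r + H * c] = sample_bilinear(src, H, W, sy, sx);
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  NumericVector out(Dimension(out_h, out_w, C));
  double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int ch = 0; ch < C; ++ch) {
    const double* src = img.begin() + (size_t)H * W * ch;
    double* dst = out.begin() + (size_t)out_h * out_w * ch;
    for (int c = 0; c < out_w; ++c)
      for (int r = 0; r < out_h; ++r) {
        double y = (r + 0.5) * sy - 0.5, x = (c + 0.5) * sx - 0.5;
        dst[r + out_h * c] = sample_bilinear(src, H, W, y, x);
      }
  }
  return out;
}

// 4-connected component labelling of a logical mask; labels start at 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + H * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int nr = pr + dr[k], nc = pc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && !lab(nr, nc)) {
            lab(nr, nc) = next;
            stack.push_back(nr + H * nc);
          }
        }
      }
    }
  return lab;
}
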
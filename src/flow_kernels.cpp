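#include <Rcpp.h>
using namespace Rcpp;

// Bilinear backward warp: out(r,c) = img sampled at (r + dy(r,c), c + dx(r,c)),
// sample coordinates clamped to the image border (replicate padding).
// [[Rcpp::export]]
NumericMatrix warp_bilinear_cpp(const NumericMatrix& img,
                                const NumericMatrix& dx,
                                const NumericMatrix& dy) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double sr = r + dy(r, c);
      double sc = c + dx(r, c);
      if (sr < 0) sr = 0; else if (sr > H - 1) sr = H - 1;
      if (sc < 0) sc = 0; else if (sc > W - 1) sc = W - 1;
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      if (r0 > H - 2) r0 = H - 2; if (r0 < 0) r0 = 0;
      if (c0 > W - 2) c0 = W - 2; if (c0 < 0) c0 = 0;
      double fr = sr - r0, fc = sc - c0;
      out(r, c) =
        (1 - fr) * (1 - fc) * img(r0, c0) +
        fr * (1 - fc) * img(r0 + 1, c0) +
        (1 - fr) * fc * img(r0, c0 + 1) +
        fr * fc * img(r0 + 1, c0 + 1);
    }
  }
  return out;
}

// Windowed sum over a (2r+1)^2 box, windows truncated at the border.
// [[Rcpp::export]]
NumericMatrix box_sum_cpp(const NumericMatrix& m, const int radius) {
  const int H = m.nrow(), W = m.ncol();
  // column pass
  NumericMatrix tmp(H, W);
  for (int c = 0; c < W; ++c) {
    double acc = 0;
    for (int r = 0; r <= std::min(radius, H - 1); ++r) acc += m(r, c);
    tmp(0, c) = acc;
    for (int r = 1; r < H; ++r) {
      if (r + radius < H) acc += m(r + radius, c);
      if (r - radius - 1 >= 0) acc -= m(r - radius - 1, c);
      tmp(r, c) = acc;
    }
  }
  NumericMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    double acc = 0;
    for (int c = 0; c <= std::min(radius, W - 1); ++c) acc += tmp(r, c);
    out(r, 0) = acc;
    for (int c = 1; c < W; ++c) {
      if (c + radius < W) acc += tmp(r, c + radius);
      if (c - radius - 1 >= 0) acc -= tmp(r, c - radius - 1);
      out(r, c) = acc;
    }
  }
  return out;
}

// Separable convolution with an odd-length kernel, replicate padding.
// [[Rcpp::export]]
NumericMatrix sep_conv_cpp(const NumericMatrix& m, const NumericVector& kernel) {
  const int H = m.nrow(), W = m.ncol();
  const int k = kernel.size(), rad = (k - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = 0; i < k; ++i) {
        int rr = r + i - rad;
        if (rr < 0) rr = 0; else if (rr > H - 1) rr = H - 1;
        acc += kernel[i] * m(rr, c);
      }
      tmp(r, c) = acc;
    }
  }
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double acc = 0;
      for (int i = 0; i < k; ++i) {
        int cc = c + i - rad;
        if (cc < 0) cc = 0; else if (cc > W - 1) cc = W - 1;
        acc += kernel[i] * tmp(r, cc);
      }
      out(r, c) = acc;
    }
  }
  return out;
}
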
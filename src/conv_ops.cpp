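// Compute kernels for backbone forward passes: im2col convolution and
// pooling over H x W x C arrays (column-major, matching R array layout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// x: H x W x C input; w: (kh*kw*C) x F weight matrix flattened from an
// R array of dim (kh, kw, C, F); zero padding (pt, pb, pl, pr).
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      int kh, int kw, int stride,
                      int pt, int pb, int pl, int pr) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  const int F = w.n_cols;
  if ((int)w.n_rows != kh * kw * C)
    stop("conv2d_fwd: weight rows (%d) != kh*kw*C (%d)", (int)w.n_rows, kh * kw * C);
  if (Ho < 1 || Wo < 1) stop("conv2d_fwd: non-positive output size");

  arma::mat patches(Ho * Wo, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int q = dh + kh * (dw + kw * c);
        double* col = patches.colptr(q);
        for (int j = 0; j < Wo; ++j) {
          const int wx = j * stride - pl + dw;
          if (wx < 0 || wx >= W) continue;
          const double* src = sl.colptr(wx);
          const int base = j * Ho;
          for (int i = 0; i < Ho; ++i) {
            const int hy = i * stride - pt + dh;
            if (hy < 0 || hy >= H) continue;
            col[base + i] = src[hy];
          }
        }
      }
    }
  }
  arma::mat out = patches * w;  // (Ho*Wo) x F
  arma::cube res(Ho, Wo, F);
  std::memcpy(res.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return res;
}

// [[Rcpp::export]]
arma::cube maxpool_fwd(const arma::cube& x, int kh, int kw, int stride,
                       int pt, int pb, int pl, int pr) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool_fwd: non-positive output size");
  arma::cube res(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    arma::mat& os = res.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double m = -std::numeric_limits<double>::infinity();
        for (int dw = 0; dw < kw; ++dw) {
          const int wx = j * stride - pl + dw;
          if (wx < 0 || wx >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hy = i * stride - pt + dh;
            if (hy < 0 || hy >= H) continue;
            const double v = sl.at(hy, wx);
            if (v > m) m = v;
          }
        }
        os.at(i, j) = m;
      }
    }
  }
  return res;
}

// Average pooling over valid (unpadded) positions only.
// [[Rcpp::export]]
arma::cube avgpool_fwd(const arma::cube& x, int kh, int kw, int stride,
                       int pt, int pb, int pl, int pr) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + pt + pb - kh) / stride + 1;
  const int Wo = (W + pl + pr - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("avgpool_fwd: non-positive output size");
  arma::cube res(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& sl = x.slice(c);
    arma::mat& os = res.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double s = 0.0;
        int n = 0;
        for (int dw = 0; dw < kw; ++dw) {
          const int wx = j * stride - pl + dw;
          if (wx < 0 || wx >= W) continue;
          for (int dh = 0; dh < kh; ++dh) {
            const int hy = i * stride - pt + dh;
            if (hy < 0 || hy >= H) continue;
            s += sl.at(hy, wx);
            ++n;
          }
        }
        os.at(i, j) = (n > 0) ? s / n : 0.0;
      }
    }
  }
  return res;
}

// Bilinear resize of a single-channel H x W image to ho x wo
// (align-corners = FALSE convention).
// [[Rcpp::export]]
arma::mat bilinear_resize(const arma::mat& x, int ho, int wo) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat out(ho, wo);
  const double sy = (double)H / ho, sx = (double)W / wo;
  for (int j = 0; j < wo; ++j) {
    double fx = (j + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > W - 1) fx = W - 1;
    const int x0 = (int)std::floor(fx);
    const int x1 = std::min(x0 + 1, W - 1);
    const double wx1 = fx - x0;
    for (int i = 0; i < ho; ++i) {
      double fy = (i + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      const int y0 = (int)std::floor(fy);
      const int y1 = std::min(y0 + 1, H - 1);
      const double wy1 = fy - y0;
      out.at(i, j) =
        (1 - wy1) * ((1 - wx1) * x.at(y0, x0) + wx1 * x.at(y0, x1)) +
        wy1 * ((1 - wx1) * x.at(y1, x0) + wx1 * x.at(y1, x1));
    }
  }
  return out;
}
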
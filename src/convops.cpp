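// Low-level 2D network kernels: same-padded (optionally dilated/strided)
// cross-correlation via im2col + GEMM, 2x2 max pooling, and fixed-kernel
// transposed convolution used for bilinear upsampling. Layouts follow R's
// column-major arrays: feature maps are (H, W, C) cubes, weight matrices are
// (kh*kw*Cin) x Cout with index u + kh*(v + kw*c) down the rows, matching
// an R array of dim c(kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static mat im2col(const cube& x, int kh, int kw, int stride, int dil,
                  int Ho, int Wo, int pad_h, int pad_w) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat M(Ho * (sword)Wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int col = u + kh * (v + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride - pad_w + v * dil;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int hi = i * stride - pad_h + u * dil;
            if (hi < 0 || hi >= H) continue;
            M(i + (sword)Ho * j, col) = x(hi, wj, c);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int kh, int kw,
                          int stride, int dil) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int pad_h = dil * (kh - 1) / 2, pad_w = dil * (kw - 1) / 2;
  const int Ho = (H + 2 * pad_h - (dil * (kh - 1) + 1)) / stride + 1;
  const int Wo = (Wd + 2 * pad_w - (dil * (kw - 1) + 1)) / stride + 1;
  const int Cout = W.n_cols;
  mat M = im2col(x, kh, kw, stride, dil, Ho, Wo, pad_h, pad_w);
  mat out = M * W;
  out.each_row() += b.t();
  cube res(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    res.slice(c) = reshape(out.col(c), Ho, Wo);
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dout, int kh, int kw,
                          int stride, int dil) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int pad_h = dil * (kh - 1) / 2, pad_w = dil * (kw - 1) / 2;
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  mat G(Ho * (sword)Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    G.col(c) = vectorise(dout.slice(c));
  mat M = im2col(x, kh, kw, stride, dil, Ho, Wo, pad_h, pad_w);
  mat dW = M.t() * G;
  vec db = sum(G, 0).t();
  mat dcol = G * W.t();          // (Ho*Wo) x (kh*kw*C)
  cube dx(H, Wd, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int col = u + kh * (v + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride - pad_w + v * dil;
          if (wj < 0 || wj >= Wd) continue;
          for (int i = 0; i < Ho; ++i) {
            const int hi = i * stride - pad_h + u * dil;
            if (hi < 0 || hi >= H) continue;
            dx(hi, wj, c) += dcol(i + (sword)Ho * j, col);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled maps and
// the within-window argmax (0..3, column-major within the window).
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int arg = 0;
        for (int dv = 0; dv < 2; ++dv)
          for (int du = 0; du < 2; ++du) {
            const double v = x(2 * i + du, 2 * j + dv, c);
            if (v > best) { best = v; arg = du + 2 * dv; }
          }
        out(i, j, c) = best;
        idx[i + (sword)Ho * (j + (sword)Wo * c)] = arg;
      }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dout, const IntegerVector& idx,
                           int H, int W) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int arg = idx[i + (sword)Ho * (j + (sword)Wo * c)];
        dx(2 * i + arg % 2, 2 * j + arg / 2, c) += dout(i, j, c);
      }
  return dx;
}

// Transposed convolution with one shared (non-learned) 2D kernel applied
// channel-wise; stride = factor, crop (k - f)/2 on each border so the
// output is exactly (H*f, W*f, C).
// [[Rcpp::export]]
arma::cube cpp_upsample_fwd(const arma::cube& x, const arma::mat& K, int f) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int k = K.n_rows, pad = (k - f) / 2;
  cube out(H * f, W * f, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double xv = x(i, j, c);
        if (xv == 0.0) continue;
        for (int v = 0; v < k; ++v) {
          const int xo = f * j - pad + v;
          if (xo < 0 || xo >= W * f) continue;
          for (int u = 0; u < k; ++u) {
            const int yo = f * i - pad + u;
            if (yo < 0 || yo >= H * f) continue;
            out(yo, xo, c) += xv * K(u, v);
          }
        }
      }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_bwd(const arma::cube& dout, const arma::mat& K,
                            int f, int H, int W) {
  const int C = dout.n_slices;
  const int k = K.n_rows, pad = (k - f) / 2;
  const int Hf = dout.n_rows, Wf = dout.n_cols;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0.0;
        for (int v = 0; v < k; ++v) {
          const int xo = f * j - pad + v;
          if (xo < 0 || xo >= Wf) continue;
          for (int u = 0; u < k; ++u) {
            const int yo = f * i - pad + u;
            if (yo < 0 || yo >= Hf) continue;
            s += K(u, v) * dout(yo, xo, c);
          }
        }
        dx(i, j, c) = s;
      }
  return dx;
}
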
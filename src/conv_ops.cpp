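// Minimal convolution / pooling kernels for the tile classifier and the
// autoencoder.  Batches are 4-D arrays in R's column-major layout
// (H, W, C, N); weights are (kh, kw, Cin, Cout).  Convolutions are realised
// as im2col + GEMM so that a single BLAS call does the heavy lifting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col_one(const double *x, int H, int W, int C,
                                   int kh, int kw, int stride, int pad,
                                   int OH, int OW) {
  arma::mat col(OH * OW, kh * kw * C);
  for (int ch = 0; ch < C; ++ch) {
    const double *xc = x + (size_t)H * W * ch;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int cidx = ki + kh * (kj + kw * ch);
        double *dst = col.colptr(cidx);
        for (int ox = 0; ox < OW; ++ox) {
          int wx = ox * stride + kj - pad;
          for (int oy = 0; oy < OH; ++oy) {
            int wy = oy * stride + ki - pad;
            double v = 0.0;
            if (wy >= 0 && wy < H && wx >= 0 && wx < W)
              v = xc[wy + (size_t)H * wx];
            dst[oy + (size_t)OH * ox] = v;
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_one(const arma::mat &col, double *gx, int H, int W,
                              int C, int kh, int kw, int stride, int pad,
                              int OH, int OW) {
  for (int ch = 0; ch < C; ++ch) {
    double *gc = gx + (size_t)H * W * ch;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int cidx = ki + kh * (kj + kw * ch);
        const double *src = col.colptr(cidx);
        for (int ox = 0; ox < OW; ++ox) {
          int wx = ox * stride + kj - pad;
          if (wx < 0 || wx >= W) continue;
          for (int oy = 0; oy < OH; ++oy) {
            int wy = oy * stride + ki - pad;
            if (wy < 0 || wy >= H) continue;
            gc[wy + (size_t)H * wx] += src[oy + (size_t)OH * ox];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (Ci != C) stop("channel mismatch between input and kernel");
  int OH = (H + 2 * pad - kh) / stride + 1;
  int OW = (W + 2 * pad - kw) / stride + 1;
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * Ci, Co, false);
  NumericVector out((size_t)OH * OW * Co * N);
  out.attr("dim") = IntegerVector::create(OH, OW, Co, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
                               kh, kw, stride, pad, OH, OW);
    arma::mat o = col * Wm;
    o.each_row() += arma::rowvec(const_cast<double *>(b.begin()), Co, false);
    std::copy(o.begin(), o.end(), out.begin() + (size_t)OH * OW * Co * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gout,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"),
                gd = gout.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  int OH = gd[0], OW = gd[1];
  arma::mat Wm(const_cast<double *>(w.begin()), kh * kw * Ci, Co, false);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  arma::mat gW(kh * kw * Ci, Co, arma::fill::zeros);
  arma::rowvec gB(Co, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C,
                               kh, kw, stride, pad, OH, OW);
    arma::mat go(const_cast<double *>(gout.begin()) +
                     (size_t)OH * OW * Co * n,
                 OH * OW, Co, false);
    gW += col.t() * go;
    gB += arma::sum(go, 0);
    arma::mat gcol = go * Wm.t();
    col2im_one(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw,
               stride, pad, OH, OW);
  }
  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gw"] = gWr,
                      _["gb"] = NumericVector(gB.begin(), gB.end()));
}

// 2x2 max pooling, stride 2.  idx records, for every output element, the
// 1-based linear index of the winning input element (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = H / 2, OW = W / 2;
  NumericVector out((size_t)OH * OW * C * N);
  IntegerVector idx((size_t)OH * OW * C * N);
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ox = 0; ox < OW; ++ox)
        for (int oy = 0; oy < OH; ++oy) {
          size_t i00 = base + (2 * oy) + (size_t)H * (2 * ox);
          size_t best = i00;
          double bv = xp[i00];
          size_t cand[3] = {i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > bv) { bv = xp[cand[k]]; best = cand[k]; }
          // column-major output: oy + OH*(ox + OW*(c + C*n))
          size_t oi = (size_t)oy + (size_t)OH * (ox + (size_t)OW * (c + (size_t)C * n));
          out[oi] = bv;
          idx[oi] = (int)(best + 1);

        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gout, IntegerVector idx,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[idx[i] - 1] += gout[i];
  return gx;
}

// nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = 2 * H, OW = 2 * W;
  NumericVector out((size_t)OH * OW * C * N);
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = (size_t)H * W * (c + (size_t)C * n);
      size_t bo = (size_t)OH * OW * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = x[bi + h + (size_t)H * w];
          size_t o00 = bo + 2 * h + (size_t)OH * (2 * w);
          out[o00] = v;
          out[o00 + 1] = v;
          out[o00 + OH] = v;
          out[o00 + OH + 1] = v;
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector gout) {
  IntegerVector gd = gout.attr("dim");
  int OH = gd[0], OW = gd[1], C = gd[2], N = gd[3];
  int H = OH / 2, W = OW / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t bi = (size_t)H * W * (c + (size_t)C * n);
      size_t bo = (size_t)OH * OW * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t o00 = bo + 2 * h + (size_t)OH * (2 * w);
          gx[bi + h + (size_t)H * w] =
              gout[o00] + gout[o00 + 1] + gout[o00 + OH] + gout[o00 + OH + 1];
        }
    }
  return gx;
}

// exact GELU x * Phi(x) and its derivative Phi(x) + x * phi(x); hot path,
// so computed with std::erf rather than R's distribution functions.
// [[Rcpp::export]]
NumericVector cpp_gelu(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * M_SQRT1_2));
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_grad(NumericVector x) {
  const double inv_sqrt_2pi = 0.3989422804014327;
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double Phi = 0.5 * (1.0 + std::erf(x[i] * M_SQRT1_2));
    out[i] = Phi + x[i] * inv_sqrt_2pi * std::exp(-0.5 * x[i] * x[i]);
  }
  out.attr("dim") = x.attr("dim");
  return out;
}
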
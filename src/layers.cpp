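// Dense compute kernels for the segmentation network.
//
// Tensor layout follows R's column-major array convention throughout:
// activations are [H, W, C, N] and convolution weights are [kh, kw, Cin, Cout].
// All kernels are written for odd square kernels with "same" zero padding,
// which covers the 3x3 block convolutions and 1x1 projections used by the
// network (1x1 convolutions take a direct GEMM fast path). Backward passes
// return exact analytic gradients; correctness is pinned by
// finite-difference tests on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d [H,W,C,N] array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// im2col for one sample: rows = H*W output positions, cols = k*k*Cin,
// column order (dkh fastest, then dkw, then ci) matching R's flattening of
// a [kh, kw, Cin, Cout] weight array.
static void im2col_same(const double* x, int H, int W, int C, int k,
                        arma::mat& col) {
  int pad = k / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int jcol = dh + k * dw + k * k * c;
        double* dst = col.colptr(jcol);
        int oh = dh - pad, ow = dw - pad;
        int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
        int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        for (int w = w0; w < w1; ++w) {
          const double* src = xc + (std::ptrdiff_t)H * (w + ow) + oh;
          double* d = dst + (std::ptrdiff_t)H * w;
          for (int h = h0; h < h1; ++h) d[h] = src[h];
        }
      }
    }
  }
}

// scatter-add transpose of im2col_same
static void col2im_same(const arma::mat& col, int H, int W, int C, int k,
                        double* x) {
  int pad = k / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)H * W * c;
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int jcol = dh + k * dw + k * k * c;
        const double* src = col.colptr(jcol);
        int oh = dh - pad, ow = dw - pad;
        int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
        int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        for (int w = w0; w < w1; ++w) {
          double* dst = xc + (std::ptrdiff_t)H * (w + ow) + oh;
          const double* s = src + (std::ptrdiff_t)H * w;
          for (int h = h0; h < h1; ++h) dst[h] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2dForward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("weights must be [kh,kw,Cin,Cout]");
  int kh = wd[0], kw = wd[1], Ci = wd[2], Co = wd[3];
  if (kh != kw) stop("only square kernels supported");
  if (Ci != C) stop("input channels (%d) do not match weight Cin (%d)", C, Ci);
  int k = kh;
  const std::size_t plane = (std::size_t)H * W;

  arma::mat Wmat(const_cast<double*>(&w[0]), k * k * Ci, Co, false, true);
  NumericVector y(plane * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  const double* xp = &x[0];
  double* yp = &y[0];

  bool has_b = bias.isNotNull();
  arma::rowvec b;
  if (has_b) {
    NumericVector bb(bias);
    b = arma::rowvec(const_cast<double*>(&bb[0]), Co, true);
  }
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat xm(const_cast<double*>(xp) + plane * C * n, plane, C, false, true);
      arma::mat ym(yp + plane * Co * n, plane, Co, false, true);
      ym = xm * Wmat;
      if (has_b) ym.each_row() += b;
    }
    return y;
  }
  arma::mat col(plane, (std::size_t)k * k * Ci);
  for (int n = 0; n < N; ++n) {
    im2col_same(xp + plane * C * n, H, W, C, k, col);
    arma::mat ym(yp + plane * Co * n, plane, Co, false, true);
    ym = col * Wmat;
    if (has_b) ym.each_row() += b;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                     bool has_bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], Ci = wd[2], Co = wd[3];
  const std::size_t plane = (std::size_t)H * W;
  arma::mat Wmat(const_cast<double*>(&w[0]), k * k * Ci, Co, false, true);

  NumericVector gx(plane * C * N);
  gx.attr("dim") = x.attr("dim");
  NumericVector gw((std::size_t)k * k * Ci * Co);
  gw.attr("dim") = w.attr("dim");
  arma::mat GW(&gw[0], k * k * Ci, Co, false, true);
  NumericVector gb(Co);
  const double* xp = &x[0];
  const double* gyp = &gy[0];
  double* gxp = &gx[0];

  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      arma::mat xm(const_cast<double*>(xp) + plane * C * n, plane, C, false, true);
      arma::mat gym(const_cast<double*>(gyp) + plane * Co * n, plane, Co, false, true);
      arma::mat gxm(gxp + plane * C * n, plane, C, false, true);
      GW += xm.t() * gym;
      gxm = gym * Wmat.t();
      if (has_bias) {
        arma::rowvec s = arma::sum(gym, 0);
        for (int c = 0; c < Co; ++c) gb[c] += s[c];
      }
    }
  } else {
    arma::mat col(plane, (std::size_t)k * k * Ci);
    for (int n = 0; n < N; ++n) {
      im2col_same(xp + plane * C * n, H, W, C, k, col);
      arma::mat gym(const_cast<double*>(gyp) + plane * Co * n, plane, Co, false, true);
      GW += col.t() * gym;
      if (has_bias) {
        arma::rowvec s = arma::sum(gym, 0);
        for (int c = 0; c < Co; ++c) gb[c] += s[c];
      }
      arma::mat gcol = gym * Wmat.t();    // (H*W) x (k*k*Ci)
      col2im_same(gcol, H, W, C, k, gxp + plane * C * n);
    }
  }
  List out = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) out["gb"] = gb;
  return out;
}

// [[Rcpp::export(name = ".maxpool2Forward")]]
List maxpool2_forward(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool requires even spatial dims");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector idx((std::size_t)Ho * Wo * C * N);   // flat index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  const double* xp = &x[0];
  double* yp = &y[0];
  int* ip = &idx[0];
  std::size_t o = 0;
  std::size_t nplanes = (std::size_t)C * N;
  for (std::size_t pl = 0; pl < nplanes; ++pl) {
    std::size_t base = (std::size_t)H * W * pl;
    for (int wq = 0; wq < Wo; ++wq) {
      const double* c0 = xp + base + (std::size_t)H * (2 * wq);
      const double* c1 = c0 + H;
      for (int hq = 0; hq < Ho; ++hq) {
        int h0 = 2 * hq;
        double bv = c0[h0]; std::size_t best = base + (std::size_t)H * 2 * wq + h0;
        if (c0[h0 + 1] > bv) { bv = c0[h0 + 1]; best += 1; }
        if (c1[h0] > bv) { bv = c1[h0]; best = base + (std::size_t)H * (2 * wq + 1) + h0; }
        if (c1[h0 + 1] > bv) { bv = c1[h0 + 1]; best = base + (std::size_t)H * (2 * wq + 1) + h0 + 1; }
        yp[o] = bv; ip[o] = (int)best; ++o;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2Backward")]]
NumericVector maxpool2_backward(IntegerVector idx, NumericVector gy,
                                IntegerVector xdim) {
  std::size_t total = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(total);
  gx.attr("dim") = xdim;
  double* gxp = &gx[0];
  const double* gyp = &gy[0];
  const int* ip = &idx[0];
  R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[ip[i]] += gyp[i];
  return gx;
}

// Bilinear x2 interpolation weights along one axis: output position i samples
// source coordinate (i + 0.5)/2 - 0.5, clamped to the valid range.
static void lin_weights(int n_in, int n_out, std::vector<int>& i0,
                        std::vector<int>& i1, std::vector<double>& f) {
  i0.resize(n_out); i1.resize(n_out); f.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * n_in / (double)n_out - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int a = (int)std::floor(s);
    int b = std::min(a + 1, n_in - 1);
    i0[i] = a; i1[i] = b; f[i] = s - a;
  }
}

// [[Rcpp::export(name = ".upsample2Forward")]]
NumericVector upsample2_forward(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1; std::vector<double> fh, fw;
  lin_weights(H, Ho, h0, h1, fh);
  lin_weights(W, Wo, w0, w1, fw);
  NumericVector y((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = &x[0];
  double* yp = &y[0];
  std::vector<double> top(Ho), bot(Ho);
  std::size_t nplanes = (std::size_t)C * N;
  for (std::size_t pl = 0; pl < nplanes; ++pl) {
    const double* xs = xp + (std::size_t)H * W * pl;
    double* ys = yp + (std::size_t)Ho * Wo * pl;
    for (int w = 0; w < Wo; ++w) {
      const double* ca = xs + (std::ptrdiff_t)H * w0[w];
      const double* cb = xs + (std::ptrdiff_t)H * w1[w];
      const double gw = fw[w];
      double* out = ys + (std::ptrdiff_t)Ho * w;
      // interpolate the two source columns once, then blend rows
      for (int h = 0; h < Ho; ++h) {
        double a = ca[h0[h]] * (1 - gw) + cb[h0[h]] * gw;
        double b = ca[h1[h]] * (1 - gw) + cb[h1[h]] * gw;
        out[h] = a * (1 - fh[h]) + b * fh[h];
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2Backward")]]
NumericVector upsample2_backward(NumericVector gy) {
  int Ho, Wo, C, N; get_dims4(gy, Ho, Wo, C, N);
  int H = Ho / 2, W = Wo / 2;
  std::vector<int> h0, h1, w0, w1; std::vector<double> fh, fw;
  lin_weights(H, Ho, h0, h1, fh);
  lin_weights(W, Wo, w0, w1, fw);
  NumericVector gx((std::size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* gyp = &gy[0];
  double* gxp = &gx[0];
  std::size_t nplanes = (std::size_t)C * N;
  for (std::size_t pl = 0; pl < nplanes; ++pl) {
    double* xs = gxp + (std::size_t)H * W * pl;
    const double* ys = gyp + (std::size_t)Ho * Wo * pl;
    for (int w = 0; w < Wo; ++w) {
      const double gw = fw[w];
      double* da = xs + (std::ptrdiff_t)H * w0[w];
      double* db = xs + (std::ptrdiff_t)H * w1[w];
      const double* in = ys + (std::ptrdiff_t)Ho * w;
      for (int h = 0; h < Ho; ++h) {
        double g = in[h];
        da[h0[h]] += g * (1 - fh[h]) * (1 - gw);
        da[h1[h]] += g * fh[h] * (1 - gw);
        db[h0[h]] += g * (1 - fh[h]) * gw;
        db[h1[h]] += g * fh[h] * gw;
      }
    }
  }
  return gx;
}

// Batch normalization over (H, W, N) per channel, training mode (batch stats).
// [[Rcpp::export(name = ".bnForward")]]
List bn_forward(NumericVector x, NumericVector gamma, NumericVector beta,
                double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const std::size_t plane = (std::size_t)H * W;
  const double m = (double)plane * N;
  NumericVector mean(C), invstd(C), var(C);
  const double* xp = &x[0];
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + plane * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < plane; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    double mu = s / m;
    double v = s2 / m - mu * mu;
    if (v < 0) v = 0;
    mean[c] = mu; var[c] = v; invstd[c] = 1.0 / std::sqrt(v + eps);
  }
  NumericVector xhat(x.size()), y(x.size());
  xhat.attr("dim") = x.attr("dim");
  y.attr("dim") = x.attr("dim");
  double* xh = &xhat[0];
  double* yp = &y[0];
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* xs = xp + off;
      double* xhs = xh + off;
      double* ysl = yp + off;
      for (std::size_t i = 0; i < plane; ++i) {
        double h = (xs[i] - mu) * is;
        xhs[i] = h;
        ysl[i] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["var"] = var, _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".bnForwardInference")]]
NumericVector bn_forward_inference(NumericVector x, NumericVector gamma,
                                   NumericVector beta, NumericVector rmean,
                                   NumericVector rvar, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const std::size_t plane = (std::size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = &x[0];
  double* yp = &y[0];
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rvar[c] + eps);
    const double g = gamma[c], b = beta[c], mu = rmean[c];
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* xs = xp + off;
      double* ys = yp + off;
      for (std::size_t i = 0; i < plane; ++i)
        ys[i] = g * (xs[i] - mu) * is + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bnBackward")]]
List bn_backward(NumericVector xhat, NumericVector invstd, NumericVector gamma,
                 NumericVector gy) {
  int H, W, C, N; get_dims4(xhat, H, W, C, N);
  const std::size_t plane = (std::size_t)H * W;
  const double m = (double)plane * N;
  NumericVector ggamma(C), gbeta(C);
  const double* xh = &xhat[0];
  const double* gp = &gy[0];
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* xs = xh + off;
      const double* gs = gp + off;
      for (std::size_t i = 0; i < plane; ++i) {
        sg += gs[i] * xs[i];
        sb += gs[i];
      }
    }
    ggamma[c] = sg; gbeta[c] = sb;
  }
  NumericVector gx(xhat.size());
  gx.attr("dim") = xhat.attr("dim");
  double* gxp = &gx[0];
  for (int c = 0; c < C; ++c) {
    const double k = gamma[c] * invstd[c] / m;
    const double sg = ggamma[c], sb = gbeta[c];
    for (int n = 0; n < N; ++n) {
      const std::size_t off = plane * (c + (std::size_t)C * n);
      const double* xs = xh + off;
      const double* gs = gp + off;
      double* gd = gxp + off;
      for (std::size_t i = 0; i < plane; ++i)
        gd[i] = k * (m * gs[i] - sb - xs[i] * sg);
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Fused ReLU helpers: avoid two full R-level array passes per activation.
// [[Rcpp::export(name = ".reluForward")]]
NumericVector relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = &x[0];
  double* yp = &y[0];
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".reluBackward")]]
NumericVector relu_backward(NumericVector y, NumericVector gy) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double* yp = &y[0];
  const double* gp = &gy[0];
  double* gxp = &gx[0];
  R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) gxp[i] = yp[i] > 0 ? gp[i] : 0.0;
  return gx;
}
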
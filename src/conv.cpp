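// 2D convolution primitives for the dense U-Net.
//
// Activation layout everywhere: R array (H, W, C, N), column-major.
// Weight layout: (kh, kw, Cin, Cout); bias: length Cout.
// "Same" zero padding; kernels have odd size.
//
// Convolutions are computed per image via im2col + one dgemm, so a batch
// forward/backward is a handful of BLAS-3 calls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fill Kt (H*W x kh*kw*C) with patches of x (H,W,C): row = h + H*w,
// column r = dh + kh*(dw + kw*c). With this (transposed-im2col) layout each
// (r, w) pair is a contiguous run over h, so filling is memcpy-bound.
static void im2col_t(const double* x, int H, int W, int C, int kh, int kw,
                     arma::mat& Kt) {
  const int ph = kh / 2, pw = kw / 2;
  Kt.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        double* col = Kt.colptr(r);
        const int h0 = std::max(0, ph - dh);
        const int h1 = std::min(H, H + ph - dh);  // exclusive
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - pw;
          if (iw < 0 || iw >= W) continue;
          std::memcpy(col + h0 + (size_t)H * w,
                      xc + (size_t)H * iw + (h0 + dh - ph),
                      (h1 - h0) * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add the transposed-im2col gradient dKt (H*W x kh*kw*C) onto dx.
static void col2im_t_add(const arma::mat& dKt, double* dx, int H, int W,
                         int C, int kh, int kw) {
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int r = dh + kh * (dw + kw * c);
        const double* col = dKt.colptr(r);
        const int h0 = std::max(0, ph - dh);
        const int h1 = std::min(H, H + ph - dh);
        if (h1 <= h0) continue;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - pw;
          if (iw < 0 || iw >= W) continue;
          double* __restrict__ dst = xc + (size_t)H * iw + (h0 + dh - ph);
          const double* __restrict__ srcp = col + h0 + (size_t)H * w;
          const int len = h1 - h0;
          for (int h = 0; h < len; ++h) dst[h] += srcp[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  NumericVector out((R_xlen_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin,
                     Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  arma::mat Kt((size_t)H * W, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, Kt);
    arma::mat Y = Kt * Wm;  // (H*W x Cout), matches output layout
    Y.each_row() += bv;
    std::copy(Y.memptr(), Y.memptr() + (size_t)H * W * Cout,
              out.begin() + (size_t)H * W * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)kh * kw * Cin * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector db(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin,
                     Cout, false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::rowvec dbv(db.begin(), Cout, false, true);
  arma::mat Kt((size_t)H * W, (size_t)kh * kw * Cin);
  for (int n = 0; n < N; ++n) {
    im2col_t(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, Kt);
    const arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                       (size_t)H * W, Cout, false, true);
    dWm += Kt.t() * dY;
    dbv += arma::sum(dY, 0);
    arma::mat dKt = dY * Wm.t();  // (H*W x kh*kw*Cin)
    col2im_t_add(dKt, dx.begin() + (size_t)H * W * C * n, H, W, C, kh, kw);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Requires even H and W.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);  // winner offset within (H,W) plane
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int best = 2 * h + H * (2 * w);
          double bv = plane[best];
          const int cand[3] = {2 * h + 1 + H * (2 * w), 2 * h + H * (2 * w + 1),
                               2 * h + 1 + H * (2 * w + 1)};
          for (int k = 0; k < 3; ++k)
            if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
          *op++ = bv;
          *ip++ = best;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(IntegerVector idx, NumericVector dy,
                                    IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2], N = in_dim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  const size_t npl = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* plane = dxp + (size_t)H * W * (c + (size_t)C * n);
      for (size_t k = 0; k < npl; ++k) plane[*ip++] += *dyp++;
    }
  return dx;
}

// Transposed convolution, kernel 2x2, stride 2 (non-overlapping upsampling).
// Weights (2, 2, Cin, Cout). Output (2H, 2W, Cout, N).
// [[Rcpp::export]]
NumericVector cpp_upconv2_forward(NumericVector x, NumericVector w,
                                  NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("upconv2: channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int dh = 0; dh < 2; ++dh)
    for (int dw = 0; dw < 2; ++dw) {
      arma::mat Wsub(Cin, Cout);  // gather the (dh,dw) slice of w
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          Wsub(c, o) = w[dh + 2 * (dw + 2 * (c + (size_t)Cin * o))];
      for (int n = 0; n < N; ++n) {
        const arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                          (size_t)H * W, C, false, true);
        arma::mat Y = X * Wsub;  // (H*W x Cout)
        for (int o = 0; o < Cout; ++o) {
          double* oc = out.begin() +
                       (size_t)Ho * Wo * (o + (size_t)Cout * n);
          const double* yc = Y.colptr(o);
          for (int ww = 0; ww < W; ++ww) {
            double* dst = oc + (size_t)Ho * (2 * ww + dw) + dh;
            const double* src = yc + (size_t)H * ww;
            for (int h = 0; h < H; ++h) dst[2 * h] = src[h] + b[o];
          }
        }
      }
    }
  return out;
}

// [[Rcpp::export]]
List cpp_upconv2_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cin = wd[2], Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw_out((R_xlen_t)2 * 2 * Cin * Cout);
  dw_out.attr("dim") = IntegerVector::create(2, 2, Cin, Cout);
  NumericVector db(Cout);
  for (int dh = 0; dh < 2; ++dh)
    for (int dw = 0; dw < 2; ++dw) {
      arma::mat Wsub(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          Wsub(c, o) = w[dh + 2 * (dw + 2 * (c + (size_t)Cin * o))];
      arma::mat dWsub(Cin, Cout, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        arma::mat G((size_t)H * W, Cout);  // gathered output gradient
        for (int o = 0; o < Cout; ++o) {
          const double* oc = dy.begin() +
                             (size_t)Ho * Wo * (o + (size_t)Cout * n);
          double* gc = G.colptr(o);
          for (int ww = 0; ww < W; ++ww) {
            const double* src = oc + (size_t)Ho * (2 * ww + dw) + dh;
            double* dst = gc + (size_t)H * ww;
            for (int h = 0; h < H; ++h) dst[h] = src[2 * h];
          }
        }
        const arma::mat X(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                          (size_t)H * W, C, false, true);
        arma::mat dX(dx.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                     false, true);
        dX += G * Wsub.t();
        dWsub += X.t() * G;
        arma::rowvec gs = arma::sum(G, 0);
        for (int o = 0; o < Cout; ++o) db[o] += gs(o);
      }
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          dw_out[dh + 2 * (dw + 2 * (c + (size_t)Cin * o))] = dWsub(c, o);
    }
  return List::create(_["dx"] = dx, _["dw"] = dw_out, _["db"] = db);
}


// Concatenate (H, W, C_i, N) arrays along the channel axis.
// [[Rcpp::export]]
NumericVector cpp_concat_c(List arrays) {
  const int m = arrays.size();
  std::vector<NumericVector> xs(m);
  int H = 0, W = 0, N = 0, Ctot = 0;
  std::vector<int> Cs(m);
  for (int i = 0; i < m; ++i) {
    xs[i] = as<NumericVector>(arrays[i]);
    IntegerVector d = xs[i].attr("dim");
    if (i == 0) { H = d[0]; W = d[1]; N = d[3]; }
    Cs[i] = d[2];
    Ctot += d[2];
  }
  NumericVector out((R_xlen_t)H * W * Ctot * N);
  out.attr("dim") = IntegerVector::create(H, W, Ctot, N);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    size_t off = plane * (size_t)Ctot * n;
    for (int i = 0; i < m; ++i) {
      std::memcpy(out.begin() + off, xs[i].begin() + plane * (size_t)Cs[i] * n,
                  plane * Cs[i] * sizeof(double));
      off += plane * Cs[i];
    }
  }
  return out;
}

// Split an (H, W, C, N) array into channel blocks of the given sizes.
// [[Rcpp::export]]
List cpp_split_c(NumericVector x, IntegerVector sizes) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  List out(sizes.size());
  int coff = 0;
  for (int i = 0; i < sizes.size(); ++i) {
    const int Ci = sizes[i];
    NumericVector part((R_xlen_t)H * W * Ci * N);
    part.attr("dim") = IntegerVector::create(H, W, Ci, N);
    for (int n = 0; n < N; ++n)
      std::memcpy(part.begin() + plane * (size_t)Ci * n,
                  x.begin() + plane * ((size_t)coff + (size_t)C * n),
                  plane * Ci * sizeof(double));
    coff += Ci;
    out[i] = part;
  }
  return out;
}

// Per-channel batch-norm statistics over (H, W, N); biased variance.
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t k = 0; k < plane; ++k) { s += p[k]; s2 += p[k] * p[k]; }
    }
    const double m = s / (plane * N);
    mean[c] = m;
    var[c] = s2 / (plane * N) - m * m;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = gamma * (x - mean) * invstd + beta; also returns xhat for backprop.
// [[Rcpp::export]]
List cpp_bn_apply(NumericVector x, NumericVector mean, NumericVector invstd,
                  NumericVector gamma, NumericVector beta) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)x.size()), xhat((R_xlen_t)x.size());
  y.attr("dim") = d;
  xhat.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c], g = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* __restrict__ xp = x.begin() + off;
      double* __restrict__ xh = xhat.begin() + off;
      double* __restrict__ yp = y.begin() + off;
      for (size_t k = 0; k < plane; ++k) {
        const double v = (xp[k] - mu) * is;
        xh[k] = v;
        yp[k] = g * v + bb;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Batch-norm backward (training mode, batch statistics):
// dx = gamma * invstd / m * (m dy - sum(dy) - xhat sum(dy xhat))
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector xhat, NumericVector invstd,
                     NumericVector gamma, NumericVector dy) {
  IntegerVector d = xhat.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx((R_xlen_t)xhat.size());
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* dyp = dy.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t k = 0; k < plane; ++k) {
        sdy += dyp[k];
        sdyx += dyp[k] * xh[k];
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double gis = gamma[c] * invstd[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* __restrict__ dyp = dy.begin() + off;
      const double* __restrict__ xh = xhat.begin() + off;
      double* __restrict__ dxp = dx.begin() + off;
      for (size_t k = 0; k < plane; ++k)
        dxp[k] = gis * (m * dyp[k] - sdy - xh[k] * sdyx);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Inference-mode batch norm using running statistics (no xhat kept).
// [[Rcpp::export]]
NumericVector cpp_bn_infer(NumericVector x, NumericVector mean,
                           NumericVector invstd, NumericVector gamma,
                           NumericVector beta) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y((R_xlen_t)x.size());
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c], g = gamma[c], bb = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* __restrict__ xp = x.begin() + off;
      double* __restrict__ yp = y.begin() + off;
      for (size_t k = 0; k < plane; ++k) yp[k] = g * (xp[k] - mu) * is + bb;
    }
  }
  return y;
}
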
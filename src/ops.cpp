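// Low-level array kernels for the hypercolumn attention network.
// Tensor layout throughout: column-major R arrays, images H x W x C x N
// (height fastest), conv weights kh x kw x Cin x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void im2col(const double *xn, int H, int W, int Cin,
                          int kh, int kw, int stride, int pad,
                          int Ho, int Wo, arma::mat &col) {
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int r = ky + kh * (kx + kw * c);
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= H) continue;
            col(r, oy + Ho * ox) = xn[iy + H * (ix + W * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin, P = Ho * Wo;

  arma::mat Wmat(w.begin(), K, Cout, false, true);
  NumericVector y((R_xlen_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * H * W * Cin, H, W, Cin,
           kh, kw, stride, pad, Ho, Wo, col);
    arma::mat out = col.t() * Wmat; // P x Cout
    double *yn = y.begin() + (R_xlen_t)n * P * Cout;
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      for (int p = 0; p < P; ++p) yn[p + (R_xlen_t)P * c] = out(p, c) + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xdim = x.attr("dim"), wdim = w.attr("dim");
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], N = xdim[3];
  const int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * Cin, P = Ho * Wo;

  arma::mat Wmat(w.begin(), K, Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * Cin * N);
  dx.attr("dim") = xdim;
  NumericVector dw((R_xlen_t)K * Cout);
  dw.attr("dim") = wdim;
  NumericVector db(Cout);
  arma::mat dWacc(dw.begin(), K, Cout, false, true);
  arma::mat col(K, P);

  for (int n = 0; n < N; ++n) {
    const double *dyn = dy.begin() + (R_xlen_t)n * P * Cout;
    arma::mat dY((double *)dyn, P, Cout, false, true);
    im2col(x.begin() + (R_xlen_t)n * H * W * Cin, H, W, Cin,
           kh, kw, stride, pad, Ho, Wo, col);
    dWacc += col * dY;
    for (int c = 0; c < Cout; ++c) db[c] += arma::accu(dY.col(c));
    arma::mat dCol = Wmat * dY.t(); // K x P
    double *dxn = dx.begin() + (R_xlen_t)n * H * W * Cin;
    for (int c = 0; c < Cin; ++c) {
      for (int kx = 0; kx < kw; ++kx) {
        for (int ky = 0; ky < kh; ++ky) {
          const int r = ky + kh * (kx + kw * c);
          for (int ox = 0; ox < Wo; ++ox) {
            const int ix = ox * stride + kx - pad;
            if (ix < 0 || ix >= W) continue;
            for (int oy = 0; oy < Ho; ++oy) {
              const int iy = oy * stride + ky - pad;
              if (iy < 0 || iy >= H) continue;
              dxn[iy + H * (ix + W * c)] += dCol(r, oy + Ho * ox);
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

struct BilinWeights {
  std::vector<int> i0, i1;
  std::vector<double> w1; // weight on i1; (1 - w1) on i0
};

// half-pixel-centre sampling (align_corners = FALSE), clamped at borders
static BilinWeights axis_weights(int n_in, int n_out) {
  BilinWeights bw;
  bw.i0.resize(n_out); bw.i1.resize(n_out); bw.w1.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, n_in - 1);
    bw.i0[o] = i0; bw.i1[o] = i1; bw.w1[o] = s - i0;
  }
  return bw;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xdim = x.attr("dim");
  const int H = xdim[0], W = xdim[1];
  int planes = 1;
  for (int d = 2; d < xdim.size(); ++d) planes *= xdim[d];
  BilinWeights by = axis_weights(H, Ho), bx = axis_weights(W, Wo);
  NumericVector y((R_xlen_t)Ho * Wo * planes);
  IntegerVector ydim = clone(xdim);
  ydim[0] = Ho; ydim[1] = Wo;
  y.attr("dim") = ydim;
  for (int pl = 0; pl < planes; ++pl) {
    const double *xp = x.begin() + (R_xlen_t)pl * H * W;
    double *yp = y.begin() + (R_xlen_t)pl * Ho * Wo;
    for (int ox = 0; ox < Wo; ++ox) {
      const int x0 = bx.i0[ox], x1 = bx.i1[ox];
      const double wx = bx.w1[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        const int y0 = by.i0[oy], y1 = by.i1[oy];
        const double wy = by.w1[oy];
        const double v =
          (1 - wy) * ((1 - wx) * xp[y0 + H * x0] + wx * xp[y0 + H * x1]) +
          wy * ((1 - wx) * xp[y1 + H * x0] + wx * xp[y1 + H * x1]);
        yp[oy + Ho * ox] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int H, int W) {
  IntegerVector ydim = dy.attr("dim");
  const int Ho = ydim[0], Wo = ydim[1];
  int planes = 1;
  for (int d = 2; d < ydim.size(); ++d) planes *= ydim[d];
  BilinWeights by = axis_weights(H, Ho), bx = axis_weights(W, Wo);
  NumericVector dx((R_xlen_t)H * W * planes);
  IntegerVector xdim = clone(ydim);
  xdim[0] = H; xdim[1] = W;
  dx.attr("dim") = xdim;
  for (int pl = 0; pl < planes; ++pl) {
    const double *dyp = dy.begin() + (R_xlen_t)pl * Ho * Wo;
    double *dxp = dx.begin() + (R_xlen_t)pl * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      const int x0 = bx.i0[ox], x1 = bx.i1[ox];
      const double wx = bx.w1[ox];
      for (int oy = 0; oy < Ho; ++oy) {
        const int y0 = by.i0[oy], y1 = by.i1[oy];
        const double wy = by.w1[oy];
        const double g = dyp[oy + Ho * ox];
        dxp[y0 + H * x0] += (1 - wy) * (1 - wx) * g;
        dxp[y0 + H * x1] += (1 - wy) * wx * g;
        dxp[y1 + H * x0] += wy * (1 - wx) * g;
        dxp[y1 + H * x1] += wy * wx * g;
      }
    }
  }
  return dx;
}

// Global average/max pool over H,W. Returns C x N matrices plus the 1-based
// linear H*W index of each channel's maximum (first occurrence).
// [[Rcpp::export]]
List cpp_pool_spatial(NumericVector x) {
  IntegerVector xdim = x.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int P = H * W;
  NumericMatrix avg(C, N), mx(C, N);
  IntegerMatrix which(C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *p = x.begin() + (R_xlen_t)P * (c + (R_xlen_t)C * n);
      double s = 0, m = p[0];
      int mi = 0;
      for (int i = 0; i < P; ++i) {
        s += p[i];
        if (p[i] > m) { m = p[i]; mi = i; }
      }
      avg(c, n) = s / P;
      mx(c, n) = m;
      which(c, n) = mi + 1;
    }
  }
  return List::create(_["avg"] = avg, _["max"] = mx, _["which"] = which);
}

// Channel-wise mean/max per pixel. Returns H x W x N arrays plus the 1-based
// channel index of each pixel's maximum.
// [[Rcpp::export]]
List cpp_pool_channel(NumericVector x) {
  IntegerVector xdim = x.attr("dim");
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int P = H * W;
  NumericVector avg((R_xlen_t)P * N), mx((R_xlen_t)P * N);
  IntegerVector which((R_xlen_t)P * N);
  IntegerVector odim = IntegerVector::create(H, W, N);
  avg.attr("dim") = odim; mx.attr("dim") = odim; which.attr("dim") = odim;
  for (int n = 0; n < N; ++n) {
    const double *xn = x.begin() + (R_xlen_t)n * P * C;
    double *an = avg.begin() + (R_xlen_t)n * P;
    double *mn = mx.begin() + (R_xlen_t)n * P;
    int *wn = which.begin() + (R_xlen_t)n * P;
    for (int i = 0; i < P; ++i) {
      double s = 0, m = xn[i];
      int mc = 0;
      for (int c = 0; c < C; ++c) {
        const double v = xn[i + (R_xlen_t)P * c];
        s += v;
        if (v > m) { m = v; mc = c; }
      }
      an[i] = s / C;
      mn[i] = m;
      wn[i] = mc + 1;
    }
  }
  return List::create(_["avg"] = avg, _["max"] = mx, _["which"] = which);
}

// Fused backward of the global average+max pooling head: spreads davg
// uniformly and adds dmax at each channel's argmax. davg, dmax: C x N;
// which: 1-based spatial argmax indices.
// [[Rcpp::export]]
NumericVector cpp_pool_spatial_bwd(NumericMatrix davg, NumericMatrix dmax,
                                   IntegerMatrix which, int H, int W) {
  const int C = davg.nrow(), N = davg.ncol();
  const int P = H * W;
  NumericVector dx((R_xlen_t)P * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *p = dx.begin() + (R_xlen_t)P * (c + (R_xlen_t)C * n);
      const double a = davg(c, n) / P;
      for (int i = 0; i < P; ++i) p[i] = a;
      p[which(c, n) - 1] += dmax(c, n);
    }
  }
  return dx;
}

// Rotate an H x W (x C) image about its centre by `angle` degrees
// (counter-clockwise in pixel coordinates), bilinear resampling, constant
// background fill outside the source frame.
// [[Rcpp::export]]
NumericVector cpp_rotate(NumericVector x, double angle, double bg) {
  IntegerVector xdim = x.attr("dim");
  const int H = xdim[0], W = xdim[1];
  int C = 1;
  for (int d = 2; d < xdim.size(); ++d) C *= xdim[d];
  const double th = angle * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;
  NumericVector y((R_xlen_t)H * W * C);
  y.attr("dim") = xdim;
  for (int ox = 0; ox < W; ++ox) {
    for (int oy = 0; oy < H; ++oy) {
      // inverse map: rotate by -angle about the centre
      const double dx = ox - cx, dy = oy - cy;
      const double sx = ct * dx + st * dy + cx;
      const double sy = -st * dx + ct * dy + cy;
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const double fx = sx - x0, fy = sy - y0;
      for (int c = 0; c < C; ++c) {
        const double *xc = x.begin() + (R_xlen_t)c * H * W;
        double v = 0;
        bool any = false;
        double acc = 0;
        const double wts[4] = {(1 - fy) * (1 - fx), (1 - fy) * fx,
                               fy * (1 - fx), fy * fx};
        const int xs[4] = {x0, x0 + 1, x0, x0 + 1};
        const int ys[4] = {y0, y0, y0 + 1, y0 + 1};
        for (int k = 0; k < 4; ++k) {
          double val;
          if (xs[k] < 0 || xs[k] >= W || ys[k] < 0 || ys[k] >= H) val = bg;
          else { val = xc[ys[k] + H * xs[k]]; any = true; }
          acc += wts[k] * val;
        }
        v = any ? acc : bg;
        y[oy + H * ((R_xlen_t)ox + (R_xlen_t)W * c)] = v;
      }
    }
  }
  return y;
}

// 8-connected component labelling of a logical mask (flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + H * qj);
            }
          }
        }
      }
    }
  }
  return lab;
}
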
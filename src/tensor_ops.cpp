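// Low-level tensor primitives for the segmentation network.
//
// Feature maps are R arrays of dim (H, W, C, N), column-major.  Convolutions
// are stride-1, same-size zero padding, cross-correlation orientation; the R
// layer flips kernels where true convolution semantics are required.
// im2col + GEMM keeps the hot loops inside BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::cube as_cube(const NumericVector& x, int H, int W, int C,
                                 int n) {
  // view of sample n without copy is not possible via Rcpp; copy the slice
  arma::cube out(H, W, C);
  const double* p = x.begin() + (std::size_t)n * H * W * C;
  std::copy(p, p + (std::size_t)H * W * C, out.memptr());
  return out;
}

static void im2col_into(const arma::cube& x, int kh, int kw, arma::mat& M,
                        std::size_t row0) {
  // rows [row0, row0+H*W) of M: column (a + kh*(b + kw*c)) holds
  // x(h+a-ph, w+b-pw, c), zero outside the image
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int col = a + kh * (b + kw * c);
        double* dst = M.colptr(col) + row0;
        for (int w = 0; w < W; ++w) {
          const int ws = w + b - pw;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, ph - a), h1 = std::min(H, H + ph - a);
          const double* src = x.slice_colptr(c, ws) + (h0 + a - ph);
          std::copy(src, src + (h1 - h0), dst + h0 + (std::size_t)H * w);
        }
      }
    }
  }
}

static void col2im_add_from(const arma::mat& M, int kh, int kw, arma::cube& x,
                            std::size_t row0) {
  // adjoint of im2col_into: scatter-add M's rows back into x
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        const int col = a + kh * (b + kw * c);
        const double* src = M.colptr(col) + row0;
        for (int w = 0; w < W; ++w) {
          const int ws = w + b - pw;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, ph - a), h1 = std::min(H, H + ph - a);
          double* dst = x.slice_colptr(c, ws) + (a - ph);
          const double* s = src + (std::size_t)H * w;
          for (int h = h0; h < h1; ++h) dst[h] += s[h];
        }
      }
    }
  }
}

// forward convolution for a whole batch in one GEMM; optionally returns the
// stacked im2col workspace so the backward pass can reuse it
// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                    bool keep_ws = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const std::size_t hw = (std::size_t)H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  NumericVector y(hw * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);

  NumericMatrix Mout;
  arma::mat Mbig;
  if (keep_ws) {
    Mout = NumericMatrix(N * hw, kh * kw * Cin);
  } else {
    Mbig.set_size(N * hw, kh * kw * Cin);
  }
  arma::mat Mview(keep_ws ? Mout.begin() : Mbig.memptr(),
                  (std::size_t)N * hw, kh * kw * Cin, false, true);
  Mview.zeros();
  for (int n = 0; n < N; ++n) {
    arma::cube xs = as_cube(x, H, W, Cin, n);
    im2col_into(xs, kh, kw, Mview, n * hw);
  }
  arma::mat Y = Mview * Wm;  // (N*H*W) x Cout
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co) + (std::size_t)n * hw;
      double* dst = y.begin() + ((std::size_t)n * Cout + co) * hw;
      const double bb = bias[co];
      for (std::size_t i = 0; i < hw; ++i) dst[i] = src[i] + bb;
    }
  if (keep_ws) return List::create(_["y"] = y, _["ws"] = Mout);
  return List::create(_["y"] = y);
}

// backward pass reusing the forward im2col workspace
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericMatrix ws, NumericVector w, NumericVector dy) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int H = yd[0], W = yd[1], Cout = yd[2], N = yd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2];
  const std::size_t hw = (std::size_t)H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false);
  arma::mat M(ws.begin(), (std::size_t)N * hw, kh * kw * Cin, false);

  // reorder dy (H,W,Cout,N) into the stacked (N*HW) x Cout layout
  arma::mat dY((std::size_t)N * hw, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      std::copy(dy.begin() + ((std::size_t)n * Cout + co) * hw,
                dy.begin() + ((std::size_t)n * Cout + co + 1) * hw,
                dY.colptr(co) + (std::size_t)n * hw);

  arma::mat dWm = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * Wm.t();

  NumericVector dx(hw * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  for (int n = 0; n < N; ++n) {
    arma::cube dxs(dx.begin() + (std::size_t)n * hw * Cin, H, W, Cin,
                   false, true);
    col2im_add_from(dM, kh, kw, dxs, (std::size_t)n * hw);
  }
  NumericVector dw(dWm.memptr(), dWm.memptr() + dWm.n_elem);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// transposed 2x2 stride-2 convolution: y[2i+a, 2j+b, co] += x[i,j,ci] w[a,b,ci,co]
// [[Rcpp::export]]
NumericVector cpp_convT2d_fwd(NumericVector x, NumericVector w,
                              NumericVector bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * Cin,
                H * W, Cin, false);
    for (int b = 0; b < 2; ++b) {
      for (int a = 0; a < 2; ++a) {
        // weight slice (a,b): Cin x Cout
        arma::mat Wab(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wab(ci, co) = w[a + 2 * (b + 2 * (ci + Cin * (std::size_t)co))];
        arma::mat Y = X * Wab;  // (H*W) x Cout
        for (int co = 0; co < Cout; ++co) {
          const double* src = Y.colptr(co);
          double* dst = y.begin() +
                        (std::size_t)n * Ho * Wo * Cout +
                        (std::size_t)co * Ho * Wo;
          const double bb = bias[co];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[(2 * i + a) + Ho * (2 * j + b)] = src[i + H * j] + bb;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convT2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((std::size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * Cin,
                H * W, Cin, false);
    arma::mat dX(dx.begin() + (std::size_t)n * H * W * Cin, H * W, Cin,
                 false, true);
    for (int b = 0; b < 2; ++b) {
      for (int a = 0; a < 2; ++a) {
        arma::mat dYab(H * W, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* src = dy.begin() +
                              (std::size_t)n * Ho * Wo * Cout +
                              (std::size_t)co * Ho * Wo;
          double* dst = dYab.colptr(co);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[i + H * j] = src[(2 * i + a) + Ho * (2 * j + b)];
        }
        arma::mat Wab(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wab(ci, co) = w[a + 2 * (b + 2 * (ci + Cin * (std::size_t)co))];
        dX += dYab * Wab.t();
        arma::mat dWab = X.t() * dYab;  // Cin x Cout
        for (int co = 0; co < Cout; ++co) {
          for (int ci = 0; ci < Cin; ++ci)
            dw[a + 2 * (b + 2 * (ci + Cin * (std::size_t)co))] += dWab(ci, co);
          db[co] += arma::accu(dYab.col(co));
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// max-pool with residual: pooled = window max (first occurrence in row-major
// window order wins ties); residual = x with each window's argmax zeroed.
// [[Rcpp::export]]
List cpp_maxpool_res(NumericVector x, int p) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Hp = H / p, Wp = W / p;
  NumericVector pooled((std::size_t)Hp * Wp * C * N);
  pooled.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  NumericVector residual = clone(x);
  residual.attr("dim") = xd;
  IntegerVector amax((std::size_t)Hp * Wp * C * N);  // 1-based index in (H,W) plane
  amax.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  std::size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)H * W * (c + (std::size_t)C * n);
      const double* plane = x.begin() + off;
      double* rplane = residual.begin() + off;
      for (int wj = 0; wj < Wp; ++wj) {
        for (int hi = 0; hi < Hp; ++hi) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = -1;
          // row-major scan of the window: rows first, then columns
          for (int a = 0; a < p; ++a) {
            for (int b = 0; b < p; ++b) {
              const int idx = (hi * p + a) + H * (wj * p + b);
              if (plane[idx] > best) { best = plane[idx]; bi = idx; }
            }
          }
          q = (std::size_t)(hi + Hp * (wj + (std::size_t)Wp * (c + (std::size_t)C * n)));
          pooled[q] = best;
          amax[q] = bi + 1;
          rplane[bi] = 0.0;
        }
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["residual"] = residual,
                      _["argmax"] = amax);
}

// gradient of the pooling branch: scatter dpooled into argmax positions
// [[Rcpp::export]]
NumericVector cpp_maxpool_scatter(NumericVector dpooled, IntegerVector amax,
                                  int H, int W) {
  IntegerVector pd = dpooled.attr("dim");
  const int Hp = pd[0], Wp = pd[1], C = pd[2], N = pd[3];
  NumericVector dx((std::size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (std::size_t q = 0; q < (std::size_t)dpooled.size(); ++q) {
    const std::size_t plane = q / ((std::size_t)Hp * Wp);
    dx[plane * H * W + (amax[q] - 1)] += dpooled[q];
  }
  return dx;
}

static inline int refl_idx(int i, int n) {
  while (i < 0 || i >= n) { if (i < 0) i = -i; if (i >= n) i = 2 * n - 2 - i; }
  return i;
}

// depthwise same-size cross-correlation with one 2D kernel (all channels);
// border handled by mirror reflection (default) or zero padding
// [[Rcpp::export]]
NumericVector cpp_depthwise_corr(NumericVector x, NumericMatrix k,
                                 bool reflect = true) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = k.nrow(), kw = k.ncol(), ph = kh / 2, pw = kw / 2;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int s = 0; s < C * N; ++s) {
    const double* src = x.begin() + (std::size_t)s * H * W;
    double* dst = y.begin() + (std::size_t)s * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double acc = 0.0;
        for (int b = 0; b < kw; ++b) {
          int ws = w + b - pw;
          if (ws < 0 || ws >= W) {
            if (!reflect) continue;
            ws = refl_idx(ws, W);
          }
          for (int a = 0; a < kh; ++a) {
            int hs = h + a - ph;
            if (hs < 0 || hs >= H) {
              if (!reflect) continue;
              hs = refl_idx(hs, H);
            }
            acc += src[hs + H * ws] * k(a, b);
          }
        }
        dst[h + H * w] = acc;
      }
    }
  }
  return y;
}

// exact adjoint of cpp_depthwise_corr with reflect borders: scatter-add each
// output pixel's kernel taps back onto the reflected source pixels
// [[Rcpp::export]]
NumericVector cpp_depthwise_corr_adj(NumericVector dy, NumericMatrix k) {
  IntegerVector xd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = k.nrow(), kw = k.ncol(), ph = kh / 2, pw = kw / 2;
  NumericVector dx(dy.size());
  dx.attr("dim") = xd;
  for (int s = 0; s < C * N; ++s) {
    const double* src = dy.begin() + (std::size_t)s * H * W;
    double* dst = dx.begin() + (std::size_t)s * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double g = src[h + H * w];
        if (g == 0.0) continue;
        for (int b = 0; b < kw; ++b) {
          const int ws = refl_idx(w + b - pw, W);
          for (int a = 0; a < kh; ++a) {
            const int hs = refl_idx(h + a - ph, H);
            dst[hs + H * ws] += g * k(a, b);
          }
        }
      }
    }
  }
  return dx;
}

// same-size cross-correlation of one matrix with reflect (mirror-no-repeat)
// border handling; used by Gaussian smoothing
// [[Rcpp::export]]
NumericMatrix cpp_filter2_reflect(NumericMatrix x, NumericMatrix k) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = k.nrow(), kw = k.ncol(), ph = kh / 2, pw = kw / 2;
  NumericMatrix y(H, W);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i; if (i >= n) i = 2 * n - 2 - i; }
    return i;
  };
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      double acc = 0.0;
      for (int b = 0; b < kw; ++b)
        for (int a = 0; a < kh; ++a)
          acc += x(refl(h + a - ph, H), refl(w + b - pw, W)) * k(a, b);
      y(h, w) = acc;
    }
  return y;
}
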
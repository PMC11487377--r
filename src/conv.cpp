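// Minimal 2-D convolution kernels used by the tensor tape.
//
// Layout convention (shared with the R side): an image batch is an R array
// with dim = c(H, W, C, N), i.e. the height index varies fastest.  Filter
// banks have dim = c(K, K, Cin, Cout).  Convolutions are cross-correlations
// (no kernel flip), zero padded, with a single integer stride.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col for one image: rows = K*K*C (ki fastest, then kj, then c),
// cols = Ho*Wo (ho fastest).
static void im2col(const double* x, int H, int W, int C,
                   int K, int stride, int pad, arma::mat& cols) {
  const int Ho = out_size(H, K, stride, pad);
  const int Wo = out_size(W, K, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      double* colp = cols.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
          const int w = wo * stride - pad + kj;
          for (int ki = 0; ki < K; ++ki) {
            const int h = ho * stride - pad + ki;
            const int r = ki + K * (kj + K * c);
            colp[r] = (h >= 0 && h < H && w >= 0 && w < W)
              ? x[h + H * (w + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int K, int stride, int pad, double* dx) {
  const int Ho = out_size(H, K, stride, pad);
  const int Wo = out_size(W, K, stride, pad);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      const double* colp = cols.colptr(p);
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          for (int ki = 0; ki < K; ++ki) {
            const int h = ho * stride - pad + ki;
            if (h < 0 || h >= H) continue;
            dx[h + H * (w + W * c)] += colp[ki + K * (kj + K * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);
  if (Ho < 1 || Wo < 1) stop("spatial size too small for kernel");

  arma::mat Wm(w.begin(), K * K * C, Cout, false, true);
  arma::vec bv(b.begin(), Cout, false, true);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  // one im2col buffer and one GEMM for the whole batch
  arma::mat cols(K * K * C, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    arma::mat sub(cols.colptr((size_t)n * Ho * Wo), K * K * C, Ho * Wo,
                  false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad, sub);
  }
  arma::mat yall = Wm.t() * cols;          // Cout x (Ho*Wo*N)
  yall.each_col() += bv;
  for (int n = 0; n < N; ++n) {
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        yp[p + Ho * Wo * co] = yall(co, (size_t)n * Ho * Wo + p);
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = out_size(H, K, stride, pad), Wo = out_size(W, K, stride, pad);

  arma::mat Wm(w.begin(), K * K * C, Cout, false, true);
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat dWm(dw.begin(), K * K * C, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);

  arma::mat cols(K * K * C, (size_t)Ho * Wo * N);
  arma::mat dyn(Cout, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        dyn(co, (size_t)n * Ho * Wo + p) = dyp[p + Ho * Wo * co];
    arma::mat sub(cols.colptr((size_t)n * Ho * Wo), K * K * C, Ho * Wo,
                  false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, K, stride, pad, sub);
  }
  dWm = cols * dyn.t();
  dbv = arma::sum(dyn, 1);
  if (need_dx) {
    arma::mat dcols = Wm * dyn;            // (K*K*C) x (Ho*Wo*N)
    for (int n = 0; n < N; ++n)
      col2im(arma::mat(dcols.colptr((size_t)n * Ho * Wo), K * K * C,
                       Ho * Wo, false, true),
             H, W, C, K, stride, pad, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = (need_dx ? (SEXP)dx : R_NilValue),
                      _["dw"] = dw, _["db"] = db);
}

// Depthwise 3x3 (or KxK) convolution, stride 1, same padding.
// x: (H, W, C, N); w: (K, K, C); b: length C.
// [[Rcpp::export(name = ".cpp_dwconv_fwd")]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], pad = (K - 1) / 2;
  NumericVector y(x.size()); y.attr("dim") = xd;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* wp = w.begin() + (size_t)c * K * K;
      double* yp = y.begin() + (size_t)(c + (size_t)n * C) * H * W;
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          double acc = b[c];
          for (int kj = 0; kj < K; ++kj) {
            const int ww = wo - pad + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              const int hh = ho - pad + ki;
              if (hh < 0 || hh >= H) continue;
              acc += xp[hh + H * ww] * wp[ki + K * kj];
            }
          }
          yp[ho + H * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_bwd")]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], pad = (K - 1) / 2;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* wp = w.begin() + (size_t)c * K * K;
      const double* dyp = dy.begin() + (size_t)(c + (size_t)n * C) * H * W;
      double* dxp = dx.begin() + (size_t)(c + (size_t)n * C) * H * W;
      double* dwp = dw.begin() + (size_t)c * K * K;
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const double g = dyp[ho + H * wo];
          db[c] += g;
          for (int kj = 0; kj < K; ++kj) {
            const int ww = wo - pad + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              const int hh = ho - pad + ki;
              if (hh < 0 || hh >= H) continue;
              dwp[ki + K * kj] += xp[hh + H * ww] * g;
              dxp[hh + H * ww] += wp[ki + K * kj] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise KxK convolution on channel-last layout: x (H, W, N, C),
// w (K, K, C), b (C); stride 1, same padding.
// [[Rcpp::export(name = ".cpp_dwconv_nc_fwd")]]
NumericVector cpp_dwconv_nc_fwd(NumericVector x, NumericVector w,
                                NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int K = wd[0], pad = (K - 1) / 2;
  NumericVector y(x.size()); y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    const double* wp = w.begin() + (size_t)c * K * K;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)c * N + n) * H * W;
      double* yp = y.begin() + ((size_t)c * N + n) * H * W;
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          double acc = b[c];
          for (int kj = 0; kj < K; ++kj) {
            const int ww = wo - pad + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              const int hh = ho - pad + ki;
              if (hh < 0 || hh >= H) continue;
              acc += xp[hh + H * ww] * wp[ki + K * kj];
            }
          }
          yp[ho + H * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_dwconv_nc_bwd")]]
List cpp_dwconv_nc_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  const int K = wd[0], pad = (K - 1) / 2;
  NumericVector dx(x.size()); dx.attr("dim") = xd;
  NumericVector dw(w.size()); dw.attr("dim") = wd;
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    const double* wp = w.begin() + (size_t)c * K * K;
    double* dwp = dw.begin() + (size_t)c * K * K;
    for (int n = 0; n < N; ++n) {
      const double* xp = x.begin() + ((size_t)c * N + n) * H * W;
      const double* dyp = dy.begin() + ((size_t)c * N + n) * H * W;
      double* dxp = dx.begin() + ((size_t)c * N + n) * H * W;
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          const double g = dyp[ho + H * wo];
          db[c] += g;
          for (int kj = 0; kj < K; ++kj) {
            const int ww = wo - pad + kj;
            if (ww < 0 || ww >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              const int hh = ho - pad + ki;
              if (hh < 0 || hh >= H) continue;
              dwp[ki + K * kj] += xp[hh + H * ww] * g;
              dxp[hh + H * ww] += wp[ki + K * kj] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
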
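#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Tensors are R arrays with dim (C, H, W, N), column-major, so the channel
// index is fastest.  All kernels stay in double precision; the matrix
// multiplications happen in R through BLAS.

static inline int out_size(int in, int k, int s, int p, int d) {
  return (in + 2 * p - d * (k - 1) - 1) / s + 1;
}

// Unfold (C,H,W,N) into a (C*kh*kw) x (Hout*Wout*N) matrix.  Row index is
// c + C*(i + kh*j); column index is oh + Hout*(ow + Wout*n), which lets the
// conv output reshape straight into dim (Cout, Hout, Wout, N).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Hout = out_size(H, kh, sh, ph, dh);
  const int Wout = out_size(W, kw, sw, pw, dw);
  if (Hout < 1 || Wout < 1)
    stop("kernel larger than padded input");
  const int K = C * kh * kw;
  NumericMatrix col(K, (R_xlen_t)Hout * Wout * N);
  const double* px = REAL(x);
  double* pc = REAL(col);
  for (int n = 0; n < N; ++n) {
    const double* xn = px + (size_t)n * C * H * W;
    for (int ow = 0; ow < Wout; ++ow) {
      const int w0 = ow * sw - pw;
      for (int oh = 0; oh < Hout; ++oh) {
        const int h0 = oh * sh - ph;
        double* dst = pc + ((size_t)oh + (size_t)Hout * (ow + (size_t)Wout * n)) * K;
        for (int j = 0; j < kw; ++j) {
          const int wi = w0 + j * dw;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i * dh;
            double* d = dst + (size_t)C * (i + kh * j);
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
              std::memcpy(d, xn + (size_t)C * (hi + (size_t)H * wi),
                          C * sizeof(double));
            } else {
              std::memset(d, 0, C * sizeof(double));
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add the column gradient back onto the input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, IntegerVector dims,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Hout = out_size(H, kh, sh, ph, dh);
  const int Wout = out_size(W, kw, sw, pw, dw);
  const int K = C * kh * kw;
  NumericVector dx((R_xlen_t)C * H * W * N);
  double* px = REAL(dx);
  const double* pc = REAL(dcol);
  for (int n = 0; n < N; ++n) {
    double* xn = px + (size_t)n * C * H * W;
    for (int ow = 0; ow < Wout; ++ow) {
      const int w0 = ow * sw - pw;
      for (int oh = 0; oh < Hout; ++oh) {
        const int h0 = oh * sh - ph;
        const double* src = pc + ((size_t)oh + (size_t)Hout * (ow + (size_t)Wout * n)) * K;
        for (int j = 0; j < kw; ++j) {
          const int wi = w0 + j * dw;
          if (wi < 0 || wi >= W) continue;
          for (int i = 0; i < kh; ++i) {
            const int hi = h0 + i * dh;
            if (hi < 0 || hi >= H) continue;
            double* d = xn + (size_t)C * (hi + (size_t)H * wi);
            const double* s = src + (size_t)C * (i + kh * j);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Max pooling; also returns the (1-based) flat argmax index per output
// element so the backward pass is a plain scatter.  Padded positions never
// win (they are treated as -Inf).
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, IntegerVector dims,
                 int kh, int kw, int sh, int sw, int ph, int pw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Hout = out_size(H, kh, sh, ph, 1);
  const int Wout = out_size(W, kw, sw, pw, 1);
  if (Hout < 1 || Wout < 1) stop("kernel larger than padded input");
  NumericVector out((R_xlen_t)C * Hout * Wout * N);
  IntegerVector arg((R_xlen_t)C * Hout * Wout * N);
  const double* px = REAL(x);
  double* po = REAL(out);
  int* pa = INTEGER(arg);
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ow = 0; ow < Wout; ++ow) {
      const int w0 = ow * sw - pw;
      for (int oh = 0; oh < Hout; ++oh) {
        const int h0 = oh * sh - ph;
        const size_t obase = (size_t)C * (oh + (size_t)Hout * (ow + (size_t)Wout * n));
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; size_t bidx = 0;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              const size_t idx = xoff + c + (size_t)C * (hi + (size_t)H * wi);
              if (px[idx] > best) { best = px[idx]; bidx = idx; }
            }
          }
          po[obase + c] = best;
          pa[obase + c] = (int)(bidx + 1);
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Hout, Wout, N);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dout, IntegerVector argmax,
                                   R_xlen_t n_in) {
  NumericVector dx(n_in);
  double* pd = REAL(dx);
  const double* pg = REAL(dout);
  const int* pa = INTEGER(argmax);
  const R_xlen_t n = dout.size();
  for (R_xlen_t k = 0; k < n; ++k) pd[pa[k] - 1] += pg[k];
  return dx;
}

// SoftPool (softmax-of-activations weighted mean) over each window.
// Padded positions are excluded from the index set R, so the output is a
// convex combination of valid inputs only.  The per-window max is subtracted
// before exponentiation; by shift invariance of softmax weights this is
// exact, not an approximation.
// [[Rcpp::export]]
NumericVector cpp_softpool(NumericVector x, IntegerVector dims,
                           int kh, int kw, int sh, int sw, int ph, int pw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Hout = out_size(H, kh, sh, ph, 1);
  const int Wout = out_size(W, kw, sw, pw, 1);
  if (Hout < 1 || Wout < 1) stop("kernel larger than padded input");
  NumericVector out((R_xlen_t)C * Hout * Wout * N);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ow = 0; ow < Wout; ++ow) {
      const int w0 = ow * sw - pw;
      for (int oh = 0; oh < Hout; ++oh) {
        const int h0 = oh * sh - ph;
        const size_t obase = (size_t)C * (oh + (size_t)Hout * (ow + (size_t)Wout * n));
        for (int c = 0; c < C; ++c) {
          double m = R_NegInf;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i; if (hi < 0 || hi >= H) continue;
              const double a = px[xoff + c + (size_t)C * (hi + (size_t)H * wi)];
              if (a > m) m = a;
            }
          }
          double num = 0.0, den = 0.0;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i; if (hi < 0 || hi >= H) continue;
              const double a = px[xoff + c + (size_t)C * (hi + (size_t)H * wi)];
              const double e = std::exp(a - m);
              num += e * a; den += e;
            }
          }
          po[obase + c] = num / den;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, Hout, Wout, N);
  return out;
}

// d softpool / d a_k = w_k * (1 + a_k - out); weights recomputed from x.
// [[Rcpp::export]]
NumericVector cpp_softpool_backward(NumericVector x, NumericVector dout,
                                    IntegerVector dims,
                                    int kh, int kw, int sh, int sw,
                                    int ph, int pw) {
  const int C = dims[0], H = dims[1], W = dims[2], N = dims[3];
  const int Hout = out_size(H, kh, sh, ph, 1);
  const int Wout = out_size(W, kw, sw, pw, 1);
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double* px = REAL(x);
  const double* pg = REAL(dout);
  double* pd = REAL(dx);
  for (int n = 0; n < N; ++n) {
    const size_t xoff = (size_t)n * C * H * W;
    for (int ow = 0; ow < Wout; ++ow) {
      const int w0 = ow * sw - pw;
      for (int oh = 0; oh < Hout; ++oh) {
        const int h0 = oh * sh - ph;
        const size_t obase = (size_t)C * (oh + (size_t)Hout * (ow + (size_t)Wout * n));
        for (int c = 0; c < C; ++c) {
          double m = R_NegInf;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i; if (hi < 0 || hi >= H) continue;
              const double a = px[xoff + c + (size_t)C * (hi + (size_t)H * wi)];
              if (a > m) m = a;
            }
          }
          double num = 0.0, den = 0.0;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i; if (hi < 0 || hi >= H) continue;
              const double a = px[xoff + c + (size_t)C * (hi + (size_t)H * wi)];
              const double e = std::exp(a - m);
              num += e * a; den += e;
            }
          }
          const double outv = num / den;
          const double g = pg[obase + c];
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j; if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i; if (hi < 0 || hi >= H) continue;
              const size_t idx = xoff + c + (size_t)C * (hi + (size_t)H * wi);
              const double wgt = std::exp(px[idx] - m) / den;
              pd[idx] += g * wgt * (1.0 + px[idx] - outv);
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Fused Adam update: first/second moments m, v are mutated in place (they
// are owned exclusively by the optimiser); returns the updated parameter
// vector.  c1, c2 are the bias-correction factors 1-b1^t, 1-b2^t.
// [[Rcpp::export]]
NumericVector cpp_adam_update(NumericVector p, NumericVector g,
                              NumericVector m, NumericVector v,
                              double lr, double b1, double b2,
                              double eps, double c1, double c2) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  double* pm = REAL(m); double* pv = REAL(v);
  const double* pp = REAL(p); const double* pg = REAL(g);
  double* po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
    po[i] = pp[i] - lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
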
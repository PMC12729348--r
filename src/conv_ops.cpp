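// Low-level layer primitives for the encoder-decoder segmentation network.
// All tensors use R's column-major array layout (H, W, C, N); convolution
// weights are (kh, kw, Cin, Cout). 'same' zero padding, stride 1 for 3x3
// convolutions; 2x2/stride-2 for pooling and transposed convolution.
//
// The 3x3 convolution is a direct cache-blocked kernel rather than
// im2col+GEMM: at the narrow channel widths of this network (8-128) BLAS
// GEMM runs far below peak, while a column-wise accumulator that keeps one
// output column per channel in L1 vectorizes well. Convolution arithmetic
// is single precision; parameters, activations and gradients stay double at
// the R interface (weight-gradient accumulation across columns is double).
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dim4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  return d;
}

// y(i,j,co) = b[co] + sum_{ci,ki,kj} w(ki,kj,ci,co) * x(i+ki-1, j+kj-1, ci)
// wf layout matches the R flattening: ki + 3*kj + 9*ci + 9*Cin*co.
static void conv3_direct(const float *__restrict__ xf, const float *__restrict__ wf,
                         const double *b, float *__restrict__ yf,
                         int H, int W, int Cin, int Cout, bool relu) {
  const size_t HW = static_cast<size_t>(H) * W;
  std::vector<float> acc(static_cast<size_t>(Cout) * H);
  for (int j = 0; j < W; ++j) {
    for (int co = 0; co < Cout; ++co)
      std::fill(acc.begin() + static_cast<size_t>(co) * H,
                acc.begin() + static_cast<size_t>(co + 1) * H,
                b ? static_cast<float>(b[co]) : 0.0f);
    for (int ci = 0; ci < Cin; ++ci) {
      const float *xp = xf + static_cast<size_t>(ci) * HW;
      for (int kj = 0; kj < 3; ++kj) {
        const int jj = j + kj - 1;
        if (jj < 0 || jj >= W) continue;
        const float *xcol = xp + static_cast<size_t>(jj) * H;
        for (int ki = 0; ki < 3; ++ki) {
          const int di = ki - 1;
          const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
          const int len = i1 - i0 + 1;
          const float *__restrict__ xs = xcol + i0 + di;
          const float *wp = wf + ki + 3 * kj + 9 * ci;
          for (int co = 0; co < Cout; ++co) {
            const float wv = wp[9 * Cin * co];
            float *__restrict__ a = acc.data() + static_cast<size_t>(co) * H + i0;
            for (int t = 0; t < len; ++t) a[t] += wv * xs[t];
          }
        }
      }
    }
    for (int co = 0; co < Cout; ++co) {
      float *ycol = yf + static_cast<size_t>(co) * HW + static_cast<size_t>(j) * H;
      const float *a = acc.data() + static_cast<size_t>(co) * H;
      if (relu)
        for (int i = 0; i < H; ++i) ycol[i] = a[i] > 0.0f ? a[i] : 0.0f;
      else
        for (int i = 0; i < H; ++i) ycol[i] = a[i];
    }
  }
}

// dw(ki,kj,ci,co) += sum_{i,j} x(i+ki-1, j+kj-1, ci) * dz(i,j,co)
static void conv3_dw(const float *__restrict__ xf, const float *__restrict__ dzf,
                     double *__restrict__ dw, int H, int W, int Cin, int Cout) {
  const size_t HW = static_cast<size_t>(H) * W;
  for (int j = 0; j < W; ++j) {
    for (int ci = 0; ci < Cin; ++ci) {
      const float *xp = xf + static_cast<size_t>(ci) * HW;
      for (int kj = 0; kj < 3; ++kj) {
        const int jj = j + kj - 1;
        if (jj < 0 || jj >= W) continue;
        const float *xcol = xp + static_cast<size_t>(jj) * H;
        for (int ki = 0; ki < 3; ++ki) {
          const int di = ki - 1;
          const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
          const int len = i1 - i0 + 1;
          const float *__restrict__ xs = xcol + i0 + di;
          double *dwp = dw + ki + 3 * kj + 9 * ci;
          for (int co = 0; co < Cout; ++co) {
            const float *__restrict__ dzc = dzf + static_cast<size_t>(co) * HW +
              static_cast<size_t>(j) * H + i0;
            float s = 0.0f;
            for (int t = 0; t < len; ++t) s += xs[t] * dzc[t];
            dwp[9 * Cin * co] += static_cast<double>(s);
          }
        }
      }
    }
  }
}

static void to_float(const double *src, float *dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, NumericVector w, NumericVector b,
                            bool relu = false) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3], Cout = dw[3];
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Cin) stop("weight shape mismatch");
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector y(static_cast<R_xlen_t>(HW) * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  std::vector<float> wf(9 * Cin * Cout), xf(HW * Cin), yf(HW * Cout);
  to_float(w.begin(), wf.data(), wf.size());
  for (int n = 0; n < N; ++n) {
    to_float(x.begin() + static_cast<R_xlen_t>(n) * HW * Cin, xf.data(), xf.size());
    conv3_direct(xf.data(), wf.data(), b.begin(), yf.data(), H, W, Cin, Cout, relu);
    double *yp = y.begin() + static_cast<R_xlen_t>(n) * HW * Cout;
    for (size_t i = 0; i < yf.size(); ++i) yp[i] = static_cast<double>(yf[i]);
  }
  return y;
}

// Gradients of the 3x3 convolution. `act`, when given, is the rectified
// layer output: the incoming gradient dy is masked by act > 0 (fused ReLU
// backward). dx is computed as a convolution of the masked gradient with
// the spatially rotated, channel-transposed kernel.
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, NumericVector w, NumericVector dy,
                   Nullable<NumericVector> act = R_NilValue) {
  IntegerVector dx_ = dim4(x), dw_ = dim4(w);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3], Cout = dw_[3];
  const size_t HW = static_cast<size_t>(H) * W;
  NumericVector dx(x.size());
  dx.attr("dim") = dx_;
  NumericVector dw(w.size());
  dw.attr("dim") = dw_;
  NumericVector db(Cout);
  const double *actp = nullptr;
  if (act.isNotNull()) {
    NumericVector a(act);
    if (a.size() != dy.size()) stop("activation/gradient size mismatch");
    actp = a.begin();
  }
  // rotated kernel: wr(ki,kj,co,ci) = w(2-ki, 2-kj, ci, co)
  std::vector<float> wr(9 * Cout * Cin), wf(9 * Cin * Cout);
  to_float(w.begin(), wf.data(), wf.size());
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kj = 0; kj < 3; ++kj)
        for (int ki = 0; ki < 3; ++ki)
          wr[(2 - ki) + 3 * (2 - kj) + 9 * co + 9 * Cout * ci] =
            wf[ki + 3 * kj + 9 * ci + 9 * Cin * co];
  std::vector<float> xf(HW * Cin), dzf(HW * Cout), dxf(HW * Cin);
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff = static_cast<R_xlen_t>(n) * HW * Cin;
    const R_xlen_t yoff = static_cast<R_xlen_t>(n) * HW * Cout;
    const double *dyp = dy.begin() + yoff;
    if (actp) {
      const double *ap = actp + yoff;
      for (size_t i = 0; i < dzf.size(); ++i)
        dzf[i] = ap[i] > 0.0 ? static_cast<float>(dyp[i]) : 0.0f;
    } else {
      to_float(dyp, dzf.data(), dzf.size());
    }
    for (int co = 0; co < Cout; ++co) {
      const float *dzc = dzf.data() + static_cast<size_t>(co) * HW;
      double acc = 0.0;
      for (size_t p = 0; p < HW; ++p) acc += dzc[p];
      db[co] += acc;
    }
    to_float(x.begin() + xoff, xf.data(), xf.size());
    conv3_dw(xf.data(), dzf.data(), dw.begin(), H, W, Cin, Cout);
    conv3_direct(dzf.data(), wr.data(), nullptr, dxf.data(), H, W, Cout, Cin,
                 false);
    double *dxp = dx.begin() + xoff;
    for (size_t i = 0; i < dxf.size(); ++i) dxp[i] = static_cast<double>(dxf[i]);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_pool2_fwd(NumericVector x) {
  IntegerVector d = dim4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("pooling needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t olen = static_cast<R_xlen_t>(Ho) * Wo * C * N;
  NumericVector y(olen);
  IntegerVector idx(olen);  // 0-based linear index into the x array
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  const double *xp = x.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (static_cast<R_xlen_t>(n) * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const R_xlen_t p00 = base + (2 * j) * H + 2 * i;
          R_xlen_t best = p00;
          double v = xp[p00];
          const R_xlen_t cand[3] = {p00 + 1, p00 + H, p00 + H + 1};
          for (int k = 0; k < 3; ++k)
            if (xp[cand[k]] > v) { v = xp[cand[k]]; best = cand[k]; }
          y[o] = v;
          idx[o] = static_cast<int>(best);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_pool2_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  R_xlen_t len = 1;
  for (int k = 0; k < xdim.size(); ++k) len *= xdim[k];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[idx[o]] += dy[o];
  return dx;
}

// Transposed convolution, 2x2 kernel, stride 2 (non-overlapping upsampling).
// [[Rcpp::export]]
NumericVector cpp_upconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = dim4(x), dw = dim4(w);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3], Cout = dw[3];
  if (dw[0] != 2 || dw[1] != 2 || dw[2] != Cin) stop("upconv weight shape mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const R_xlen_t xs_len = static_cast<R_xlen_t>(H) * W * Cin;
  const R_xlen_t ys_len = static_cast<R_xlen_t>(Ho) * Wo * Cout;
  const arma::cube wc(const_cast<double *>(w.begin()), 4, Cin, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const arma::mat xm(const_cast<double *>(x.begin()) + n * xs_len,
                       static_cast<R_xlen_t>(H) * W, Cin, false, true);
    for (int kj = 0; kj < 2; ++kj)
      for (int ki = 0; ki < 2; ++ki) {
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = wc(ki + 2 * kj, ci, co);
        arma::mat ym = xm * Wsub;  // (H*W) x Cout
        for (int co = 0; co < Cout; ++co) {
          double *yp = y.begin() + n * ys_len + static_cast<R_xlen_t>(co) * Ho * Wo;
          const double *src = ym.colptr(co);
          const double bc = b[co];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yp[(2 * j + kj) * Ho + (2 * i + ki)] = src[j * H + i] + bc;
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector dx_ = dim4(x), dw_ = dim4(w);
  const int H = dx_[0], W = dx_[1], Cin = dx_[2], N = dx_[3], Cout = dw_[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(x.size());
  dx.attr("dim") = dx_;
  NumericVector dw(w.size());
  dw.attr("dim") = dw_;
  NumericVector db(Cout);
  const R_xlen_t xs_len = static_cast<R_xlen_t>(H) * W * Cin;
  const R_xlen_t ys_len = static_cast<R_xlen_t>(Ho) * Wo * Cout;
  arma::cube dwc(dw.begin(), 4, Cin, Cout, false, true);
  const arma::cube wc(const_cast<double *>(w.begin()), 4, Cin, Cout, false, true);
  arma::mat dysub(static_cast<R_xlen_t>(H) * W, Cout);
  for (int n = 0; n < N; ++n) {
    const arma::mat xm(const_cast<double *>(x.begin()) + n * xs_len,
                       static_cast<R_xlen_t>(H) * W, Cin, false, true);
    arma::mat dxm(dx.begin() + n * xs_len, static_cast<R_xlen_t>(H) * W, Cin,
                  false, true);
    for (int kj = 0; kj < 2; ++kj)
      for (int ki = 0; ki < 2; ++ki) {
        for (int co = 0; co < Cout; ++co) {
          const double *dyp = dy.begin() + n * ys_len + static_cast<R_xlen_t>(co) * Ho * Wo;
          double *dst = dysub.colptr(co);
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              dst[j * H + i] = dyp[(2 * j + kj) * Ho + (2 * i + ki)];
        }
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = wc(ki + 2 * kj, ci, co);
        dxm += dysub * Wsub.t();
        arma::mat dWsub = xm.t() * dysub;  // Cin x Cout
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dwc(ki + 2 * kj, ci, co) += dWsub(ci, co);
      }
  }
  // bias gradient: dy summed over all spatial positions and the batch
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *dyp = dy.begin() + n * ys_len + static_cast<R_xlen_t>(co) * Ho * Wo;
      double acc = 0.0;
      for (R_xlen_t p = 0; p < static_cast<R_xlen_t>(Ho) * Wo; ++p) acc += dyp[p];
      db[co] += acc;
    }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
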
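// Convolution kernels for the recurrent U-Net.
//
// Tensor layout throughout: images are column-major R arrays of dimension
// (H, W, C, T) -- rows, columns, channels, frames.  Spatial kernels are
// (kh, kw, Cin, Cout), temporal kernels (kt, Cin, Cout).  Spatial
// convolution uses "same"-style zero padding p = dilation*(k-1)/2; the
// temporal convolution offers circular padding (the cine sequence is
// cyclic) or zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather one frame (H x W x Cin block at `x`) into a patch matrix
// col (Ho*Wo) x (kh*kw*Cin); column kk = ih + kh*(iw + kw*ci) matches the
// column-major flattening of the (kh, kw, Cin, Cout) weight array.
static void im2col(const double* x, int H, int W, int Cin,
                   int kh, int kw, int s, int d, int p,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        int kk = ih + kh * (iw + kw * ci);
        double* ccol = col.colptr(kk);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + iw * d;
          double* cc = ccol + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) { std::fill(cc, cc + Ho, 0.0); continue; }
          const double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + ih * d;
            cc[ho] = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the patch-matrix gradient back onto the input frame.
static void col2im(const arma::mat& gcol, double* gx, int H, int W, int Cin,
                   int kh, int kw, int s, int d, int p, int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = gx + (size_t)ci * H * W;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        int kk = ih + kh * (iw + kw * ci);
        const double* ccol = gcol.colptr(kk);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * s - p + iw * d;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)wi * H;
          const double* cc = ccol + (size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * s - p + ih * d;
            if (hi >= 0 && hi < H) xcw[hi] += cc[ho];
          }
        }
      }
    }
  }
}

static void out_dims(int H, int W, int kh, int kw, int s, int d,
                     int& p, int& Ho, int& Wo) {
  p = d * (kh - 1) / 2;
  Ho = (H + 2 * p - d * (kh - 1) - 1) / s + 1;
  Wo = (W + 2 * p - d * (kw - 1) - 1) / s + 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int dilation) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], T = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch between input and kernel");
  int p, Ho, Wo;
  out_dims(H, W, kh, kw, stride, dilation, p, Ho, Wo);
  int K = kh * kw * Cin;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout, false, true);
  NumericVector out((size_t)Ho * Wo * Cout * T);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, T);
  arma::mat col((size_t)Ho * Wo, K);
  for (int t = 0; t < T; ++t) {
    im2col(x.begin() + (size_t)t * H * W * Cin, H, W, Cin,
           kh, kw, stride, dilation, p, Ho, Wo, col);
    arma::mat O(out.begin() + (size_t)t * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    O = col * Wm;
    O.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwx(NumericVector gout, NumericVector w,
                             IntegerVector xdim, int stride, int dilation) {
  IntegerVector wd = w.attr("dim");
  int H = xdim[0], W = xdim[1], Cin = xdim[2], T = xdim[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int p, Ho, Wo;
  out_dims(H, W, kh, kw, stride, dilation, p, Ho, Wo);
  int K = kh * kw * Cin;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector gx((size_t)H * W * Cin * T);  // zero-initialised
  gx.attr("dim") = xdim;
  for (int t = 0; t < T; ++t) {
    arma::mat G(gout.begin() + (size_t)t * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    arma::mat gcol = G * Wm.t();
    col2im(gcol, gx.begin() + (size_t)t * H * W * Cin, H, W, Cin,
           kh, kw, stride, dilation, p, Ho, Wo);
  }
  return gx;
}

// [[Rcpp::export]]
List cpp_conv2d_bww(NumericVector x, NumericVector gout, IntegerVector wdim,
                    int stride, int dilation) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], T = xd[3];
  int kh = wdim[0], kw = wdim[1], Cout = wdim[3];
  int p, Ho, Wo;
  out_dims(H, W, kh, kw, stride, dilation, p, Ho, Wo);
  int K = kh * kw * Cin;
  arma::mat gw(K, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  arma::mat col((size_t)Ho * Wo, K);
  for (int t = 0; t < T; ++t) {
    im2col(x.begin() + (size_t)t * H * W * Cin, H, W, Cin,
           kh, kw, stride, dilation, p, Ho, Wo, col);
    arma::mat G(gout.begin() + (size_t)t * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    gw += col.t() * G;
    gb += arma::sum(G, 0);
  }
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = wdim;
  return List::create(_["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Temporal 1D convolution across frames; x is (H, W, Cin, T), w is
// (kt, Cin, Cout).  Circular padding wraps the sequence (frame T precedes
// frame 1); zero padding treats out-of-range frames as zero.
// [[Rcpp::export]]
NumericVector cpp_conv1d_time_fwd(NumericVector x, NumericVector w,
                                  NumericVector b, bool circular) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], T = xd[3];
  int kt = wd[0], Cout = wd[2];
  if (wd[1] != Cin) stop("channel mismatch between input and temporal kernel");
  int half = kt / 2;
  size_t N = (size_t)H * W;
  NumericVector out(N * Cout * T);
  out.attr("dim") = IntegerVector::create(H, W, Cout, T);
  arma::rowvec bv(b.begin(), Cout, false, true);
  // Unpack per-tap weight matrices (Cin x Cout).
  std::vector<arma::mat> Wk(kt);
  for (int k = 0; k < kt; ++k) {
    Wk[k].set_size(Cin, Cout);
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c)
        Wk[k](c, o) = w[k + kt * (c + (size_t)Cin * o)];
  }
  for (int t = 0; t < T; ++t) {
    arma::mat O(out.begin() + (size_t)t * N * Cout, N, Cout, false, true);
    O.each_row() = bv;
    for (int k = 0; k < kt; ++k) {
      int src = t + k - half;
      if (circular) src = ((src % T) + T) % T;
      else if (src < 0 || src >= T) continue;
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)src * N * Cin,
                  N, Cin, false, true);
      O += X * Wk[k];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv1d_time_bw(NumericVector x, NumericVector gout, NumericVector w,
                        bool circular) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], T = xd[3];
  int kt = wd[0], Cout = wd[2];
  int half = kt / 2;
  size_t N = (size_t)H * W;
  std::vector<arma::mat> Wk(kt), gWk(kt);
  for (int k = 0; k < kt; ++k) {
    Wk[k].set_size(Cin, Cout);
    gWk[k].zeros(Cin, Cout);
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c)
        Wk[k](c, o) = w[k + kt * (c + (size_t)Cin * o)];
  }
  NumericVector gx((size_t)N * Cin * T);
  gx.attr("dim") = xd;
  arma::rowvec gb(Cout, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat G(const_cast<double*>(gout.begin()) + (size_t)t * N * Cout,
                N, Cout, false, true);
    gb += arma::sum(G, 0);
    for (int k = 0; k < kt; ++k) {
      int src = t + k - half;
      if (circular) src = ((src % T) + T) % T;
      else if (src < 0 || src >= T) continue;
      arma::mat X(const_cast<double*>(x.begin()) + (size_t)src * N * Cin,
                  N, Cin, false, true);
      arma::mat GX(gx.begin() + (size_t)src * N * Cin, N, Cin, false, true);
      GX += G * Wk[k].t();
      gWk[k] += X.t() * G;
    }
  }
  NumericVector gw((size_t)kt * Cin * Cout);
  gw.attr("dim") = wd;
  for (int k = 0; k < kt; ++k)
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c)
        gw[k + kt * (c + (size_t)Cin * o)] = gWk[k](c, o);
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
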
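// Dense 2-D convolution kernels for the location-map predictor.
// Cross-correlation semantics (CNN convention), zero padding, stride 1,
// "same" output size.  Lowered to im2col + GEMM so the heavy lifting
// runs in BLAS; ample for desk-scale training on one CPU core.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Valid overlap ranges of an output grid shifted by (du, dv) against
// the input grid (everything outside is zero padding).
struct Shift {
  arma::uword yr0, yr1, yc0, yc1; // output submatrix
  arma::uword xr0, xr1, xc0, xc1; // input submatrix
  bool empty;
};

static Shift shift_ranges(int H, int W, int du, int dv) {
  Shift s;
  int yr0 = std::max(0, -du), yr1 = H - 1 - std::max(0, du);
  int yc0 = std::max(0, -dv), yc1 = W - 1 - std::max(0, dv);
  s.empty = (yr1 < yr0) || (yc1 < yc0);
  if (s.empty) return s;
  s.yr0 = yr0; s.yr1 = yr1; s.yc0 = yc0; s.yc1 = yc1;
  s.xr0 = yr0 + du; s.xr1 = yr1 + du;
  s.xc0 = yc0 + dv; s.xc1 = yc1 + dv;
  return s;
}

// Column order (u fastest, then v, then ci) matches the column-major
// layout of the (kh, kw, cin, cout) weight array, so the reshaped
// weight matrix multiplies directly.
static arma::mat im2col(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  arma::mat out(H * W, kh * kw * C, arma::fill::zeros);
  int col = 0;
  for (int ci = 0; ci < C; ++ci) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u, ++col) {
        Shift s = shift_ranges(H, W, u - ph, v - pw);
        if (s.empty) continue;
        arma::mat view(out.colptr(col), H, W, false, true);
        view.submat(s.yr0, s.yc0, s.yr1, s.yc1) =
          x.slice(ci).submat(s.xr0, s.xc0, s.xr1, s.xc1);
      }
    }
  }
  return out;
}

// x: (H, W, Cin); w: dim (kh, kw, Cin, Cout); b: length Cout
// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const NumericVector& w,
                          const arma::vec& b) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  const int H = x.n_rows, W = x.n_cols;
  const arma::mat W2(const_cast<double*>(w.begin()),
                     kh * kw * cin, cout, false, true);
  arma::mat Y = im2col(x, kh, kw) * W2;
  Y.each_row() += b.t();
  arma::cube y(H, W, cout);
  std::memcpy(y.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return y;
}

// Gradients of the same-padded cross-correlation.
// gy: (H, W, Cout).  Returns gx (H, W, Cin), gw (dim of w), gb.
// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube& x, const NumericVector& w,
                    const arma::cube& gy) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int H = x.n_rows, W = x.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  const arma::mat W2(const_cast<double*>(w.begin()),
                     kh * kw * cin, cout, false, true);
  const arma::mat gY(const_cast<double*>(gy.memptr()),
                     H * W, cout, false, true);
  arma::mat col = im2col(x, kh, kw);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  arma::mat gWm(gw.begin(), kh * kw * cin, cout, false, true);
  gWm = col.t() * gY;
  arma::vec gb = arma::sum(gY, 0).t();
  arma::mat gcol = gY * W2.t();        // (H*W, kh*kw*cin)
  arma::cube gx(H, W, cin, arma::fill::zeros);
  int c = 0;
  for (int ci = 0; ci < cin; ++ci) {   // col2im scatter-add
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u, ++c) {
        Shift s = shift_ranges(H, W, u - ph, v - pw);
        if (s.empty) continue;
        arma::mat view(gcol.colptr(c), H, W, false, true);
        gx.slice(ci).submat(s.xr0, s.xc0, s.xr1, s.xc1) +=
          view.submat(s.yr0, s.yc0, s.yr1, s.yc1);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Forward pass that also keeps the im2col matrix (as an external
// pointer, so it never round-trips through R) for the backward pass.
// [[Rcpp::export]]
List cpp_conv2d_fwd_cache(const arma::cube& x, const NumericVector& w,
                          const arma::vec& b) {
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if ((int)x.n_slices != cin) stop("input channel mismatch");
  const int H = x.n_rows, W = x.n_cols;
  const arma::mat W2(const_cast<double*>(w.begin()),
                     kh * kw * cin, cout, false, true);
  XPtr<arma::mat> colp(new arma::mat(im2col(x, kh, kw)), true);
  arma::mat Y = (*colp) * W2;
  Y.each_row() += b.t();
  arma::cube y(H, W, cout);
  std::memcpy(y.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return List::create(_["y"] = y, _["col"] = colp);
}

// Backward pass reusing a cached im2col matrix.
// [[Rcpp::export]]
List cpp_conv2d_bwd_cached(SEXP col_ptr, const NumericVector& w,
                           const arma::cube& gy) {
  XPtr<arma::mat> colp(col_ptr);
  const arma::mat& col = *colp;
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int H = gy.n_rows, W = gy.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  const arma::mat W2(const_cast<double*>(w.begin()),
                     kh * kw * cin, cout, false, true);
  const arma::mat gY(const_cast<double*>(gy.memptr()),
                     H * W, cout, false, true);
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  arma::mat gWm(gw.begin(), kh * kw * cin, cout, false, true);
  gWm = col.t() * gY;
  arma::vec gb = arma::sum(gY, 0).t();
  arma::mat gcol = gY * W2.t();
  arma::cube gx(H, W, cin, arma::fill::zeros);
  int c = 0;
  for (int ci = 0; ci < cin; ++ci) {
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u, ++c) {
        Shift s = shift_ranges(H, W, u - ph, v - pw);
        if (s.empty) continue;
        arma::mat view(gcol.colptr(c), H, W, false, true);
        gx.slice(ci).submat(s.xr0, s.xc0, s.xr1, s.xc1) +=
          view.submat(s.yr0, s.yc0, s.yr1, s.yc1);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Clipped r x r box sum via an integral image.
// [[Rcpp::export]]
arma::mat cpp_box_sum(const arma::mat& m, const int r) {
  const int p = (r - 1) / 2, H = m.n_rows, W = m.n_cols;
  arma::mat S(H + 1, W + 1, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      S(i + 1, j + 1) = m(i, j) + S(i, j + 1) + S(i + 1, j) - S(i, j);
  arma::mat out(H, W);
  for (int j = 0; j < W; ++j) {
    const int c0 = std::max(0, j - p), c1 = std::min(W - 1, j + p);
    for (int i = 0; i < H; ++i) {
      const int r0 = std::max(0, i - p), r1 = std::min(H - 1, i + p);
      out(i, j) = S(r1 + 1, c1 + 1) - S(r0, c1 + 1) -
                  S(r1 + 1, c0) + S(r0, c0);
    }
  }
  return out;
}
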
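// Low-level dense kernels for the segmentation network.
// Layout convention: feature maps are R arrays dim (H, W, C), i.e. arma::cube
// with n_rows = H, n_cols = W, n_slices = C. Convolution weights arrive as a
// (kh*kw*Cin) x Cout matrix whose row index is di + kh*(dj + kw*cin) -- the
// natural column-major flattening of an R array dim (kh, kw, Cin, Cout).
// All convolutions use odd kernels with zero "same" padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col_same(const cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat cols(H * (sword)W, kh * (sword)kw * C);
  mat padded(H + kh - 1, W + kw - 1);
  for (int c = 0; c < C; ++c) {
    padded.zeros();
    padded.submat(ph, pw, ph + H - 1, pw + W - 1) = x.slice(c);
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        int idx = di + kh * (dj + kw * c);
        cols.col(idx) = vectorise(padded.submat(di, dj, di + H - 1, dj + W - 1));
      }
  }
  return cols;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  mat cols = im2col_same(x, kh, kw);
  mat y = cols * w;
  y.each_row() += b.t();
  cube out(y.memptr(), H, W, Cout);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& w,
                          const arma::cube& dy, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = w.n_cols;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  mat dy_mat(const_cast<double*>(dy.memptr()), H * (sword)W, Cout, false, true);
  mat cols = im2col_same(x, kh, kw);
  mat dw = cols.t() * dy_mat;
  vec db = sum(dy_mat, 0).t();
  mat dcols = dy_mat * w.t();
  cube dx(H, W, Cin, fill::zeros);
  mat acc(H + kh - 1, W + kw - 1);
  for (int c = 0; c < Cin; ++c) {
    acc.zeros();
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        int idx = di + kh * (dj + kw * c);
        acc.submat(di, dj, di + H - 1, dj + W - 1) +=
          reshape(dcols.col(idx), H, W);
      }
    dx.slice(c) = acc.submat(ph, pw, ph + H - 1, pw + W - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled map and the
// 1-based linear index (into the input cube) of each selected element, so the
// backward pass can route gradients. Ties resolve to the first element scanned
// (top-left first), keeping the operation deterministic.
// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
Rcpp::List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  Rcpp::IntegerVector idx(Ho * (sword)Wo * C);
  sword plane = (sword)H * W;
  sword k = 0;
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int i0 = 2 * i, j0 = 2 * j;
        double best = s(i0, j0);
        int bi = i0, bj = j0;
        if (s(i0 + 1, j0) > best) { best = s(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (s(i0, j0 + 1) > best) { best = s(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (s(i0 + 1, j0 + 1) > best) { best = s(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        y(i, j, c) = best;
        idx[k++] = (int)(c * plane + bj * H + bi + 1);
      }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
arma::cube cpp_maxpool2_bwd(const Rcpp::IntegerVector& idx, const arma::cube& dy,
                            int H, int W) {
  const int C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  const double* g = dy.memptr();
  for (R_xlen_t k = 0; k < idx.size(); ++k)
    dx.memptr()[idx[k] - 1] += g[k];
  return dx;
}
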
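// 2-D convolution / transposed-convolution primitives for the pix2pix
// networks. Single image (no batch axis): tensors are H x W x C cubes.
// Weight layouts:
//   conv:  W  is (Cout x k*k*Cin), row-major over (channel, kx, ky) patches
//   tconv: U  is (Cin  x k*k*Cout) -- the adjoint orientation, so that a
//          transposed convolution is literally the adjoint of a strided
//          convolution with the same geometry.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gather k*k*C patch rows for every output position of a conv with
// geometry (k, stride s, zero pad p). Column index = jo*Ho + io.
static mat im2col(const cube& x, int k, int s, int p) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  mat cols(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * s - p + dj;
          if (jin < 0 || jin >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * s - p + di;
            if (iin < 0 || iin >= H) continue;
            cols(r, jo * Ho + io) = x(iin, jin, c);
          }
        }
      }
  return cols;
}

// Adjoint of im2col: scatter-add patch rows back into an (Himg x Wimg x C)
// image. ncol(cols) must equal Ho*Wo for that geometry.
static cube col2im(const mat& cols, int Himg, int Wimg, int C,
                   int k, int s, int p) {
  const int Ho = (Himg + 2 * p - k) / s + 1;
  const int Wo = (Wimg + 2 * p - k) / s + 1;
  cube x(Himg, Wimg, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        const int r = c * k * k + dj * k + di;
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * s - p + dj;
          if (jin < 0 || jin >= Wimg) continue;
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * s - p + di;
            if (iin < 0 || iin >= Himg) continue;
            x(iin, jin, c) += cols(r, jo * Ho + io);
          }
        }
      }
  return x;
}

static cube mat_to_cube(const mat& m, int H, int W) {
  // rows of m are channels, columns are jo*H + io
  cube y(H, W, m.n_rows);
  for (uword c = 0; c < m.n_rows; ++c)
    y.slice(c) = reshape(m.row(c), H, W);
  return y;
}

static mat cube_to_mat(const cube& x) {
  mat m(x.n_slices, x.n_rows * x.n_cols);
  for (uword c = 0; c < x.n_slices; ++c)
    m.row(c) = vectorise(x.slice(c)).t();
  return m;
}

// [[Rcpp::export]]
arma::cube nn_conv_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int s, int p) {
  const int Ho = ((int)x.n_rows + 2 * p - k) / s + 1;
  const int Wo = ((int)x.n_cols + 2 * p - k) / s + 1;
  mat cols = im2col(x, k, s, p);
  mat ym = w * cols;
  ym.each_col() += b;
  return mat_to_cube(ym, Ho, Wo);
}

// [[Rcpp::export]]
Rcpp::List nn_conv_bw(const arma::cube& x, const arma::mat& w,
                      const arma::cube& gy, int k, int s, int p) {
  mat cols = im2col(x, k, s, p);
  mat gym = cube_to_mat(gy);
  mat gw = gym * cols.t();
  vec gb = sum(gym, 1);
  mat gcols = w.t() * gym;
  cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, k, s, p);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube nn_tconv_fw(const arma::cube& x, const arma::mat& u,
                       const arma::vec& b, int k, int s, int p) {
  const int Ho = ((int)x.n_rows - 1) * s - 2 * p + k;
  const int Wo = ((int)x.n_cols - 1) * s - 2 * p + k;
  const int Cout = (int)u.n_cols / (k * k);
  mat xm = cube_to_mat(x);
  mat cols = u.t() * xm;
  cube y = col2im(cols, Ho, Wo, Cout, k, s, p);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List nn_tconv_bw(const arma::cube& x, const arma::mat& u,
                       const arma::cube& gy, int k, int s, int p) {
  mat gcols = im2col(gy, k, s, p);
  mat xm = cube_to_mat(x);
  mat gxm = u * gcols;
  cube gx = mat_to_cube(gxm, x.n_rows, x.n_cols);
  mat gu = xm * gcols.t();
  vec gb(gy.n_slices);
  for (uword c = 0; c < gy.n_slices; ++c) gb(c) = accu(gy.slice(c));
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gu") = gu,
                            Rcpp::Named("gb") = gb);
}
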
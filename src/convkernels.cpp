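// Minimal single-sample CNN kernels: im2col/col2im convolution, transposed
// convolution, and per-sample (instance) normalization, forward and backward.
// Layout: images are H x W x C arma::cube (column-major, matching R arrays);
// conv weights are (Cout x k*k*Cin), tconv weights are (Cin x k*k*Cout).
// Padding is given per side so "same" output with even kernels is exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Column l (0-based) = i_out + outH * j_out; row r = ki + k*kj + k*k*c.
static mat im2col_(const cube& x, int k, int stride,
                   int padT, int padL, int outH, int outW) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(k * k * C, outH * outW, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int jo = 0; jo < outW; ++jo) {
          const int j = jo * stride - padL + kj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < outH; ++io) {
            const int i = io * stride - padT + ki;
            if (i < 0 || i >= H) continue;
            cols(r, io + outH * jo) = xc(i, j);
          }
        }
      }
    }
  }
  return cols;
}

static cube col2im_(const mat& cols, int H, int W, int C, int k, int stride,
                    int padT, int padL, int outH, int outW) {
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * c;
        for (int jo = 0; jo < outW; ++jo) {
          const int j = jo * stride - padL + kj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < outH; ++io) {
            const int i = io * stride - padT + ki;
            if (i < 0 || i >= H) continue;
            xc(i, j) += cols(r, io + outH * jo);
          }
        }
      }
    }
  }
  return x;
}

static cube mat_to_cube(const mat& m, int H, int W) {
  // m is (C x H*W), columns ordered i + H*j
  cube y(H, W, m.n_rows);
  for (uword c = 0; c < m.n_rows; ++c)
    y.slice(c) = reshape(m.row(c).t(), H, W);
  return y;
}

static mat cube_to_mat(const cube& x) {
  mat m(x.n_slices, x.n_rows * x.n_cols);
  for (uword c = 0; c < x.n_slices; ++c)
    m.row(c) = vectorise(x.slice(c)).t();
  return m;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k, int stride,
                     int padT, int padL, int outH, int outW) {
  mat cols = im2col_(x, k, stride, padT, padL, outH, outW);
  mat y = w * cols;
  y.each_col() += b;
  return mat_to_cube(y, outH, outW);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dy, int k, int stride,
                     int padT, int padL) {
  const int outH = dy.n_rows, outW = dy.n_cols;
  mat cols = im2col_(x, k, stride, padT, padL, outH, outW);
  mat dy_m = cube_to_mat(dy);
  mat dw = dy_m * cols.t();
  vec db = sum(dy_m, 1);
  mat dcols = w.t() * dy_m;
  cube dx = col2im_(dcols, x.n_rows, x.n_cols, x.n_slices,
                    k, stride, padT, padL, outH, outW);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::cube tconv2d_fw(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, int k, int stride,
                      int padT, int padL, int outH, int outW) {
  mat x_m = cube_to_mat(x);                 // Cin x L
  mat cols = w.t() * x_m;                   // k*k*Cout x L
  const int Cout = w.n_cols / (k * k);
  cube y = col2im_(cols, outH, outW, Cout, k, stride, padT, padL,
                   x.n_rows, x.n_cols);
  for (int c = 0; c < Cout; ++c) y.slice(c) += b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List tconv2d_bw(const arma::cube& x, const arma::mat& w,
                      const arma::cube& dy, int k, int stride,
                      int padT, int padL) {
  mat dcols = im2col_(dy, k, stride, padT, padL, x.n_rows, x.n_cols);
  mat x_m = cube_to_mat(x);
  mat dx_m = w * dcols;                      // Cin x L
  cube dx = mat_to_cube(dx_m, x.n_rows, x.n_cols);
  mat dw = x_m * dcols.t();                  // Cin x k*k*Cout
  vec db(dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c) db(c) = accu(dy.slice(c));
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List inorm_fw(const arma::cube& x, const arma::vec& gamma,
                    const arma::vec& beta, double eps) {
  cube xhat(size(x)), y(size(x));
  vec istd(x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) {
    const double mu = mean(vectorise(x.slice(c)));
    const double va = mean(square(vectorise(x.slice(c)) - mu));
    istd(c) = 1.0 / std::sqrt(va + eps);
    xhat.slice(c) = (x.slice(c) - mu) * istd(c);
    y.slice(c) = gamma(c) * xhat.slice(c) + beta(c);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List inorm_bw(const arma::cube& dy, const arma::cube& xhat,
                    const arma::vec& istd, const arma::vec& gamma) {
  cube dx(size(dy));
  vec dgamma(dy.n_slices), dbeta(dy.n_slices);
  for (uword c = 0; c < dy.n_slices; ++c) {
    const mat& g = dy.slice(c);
    const mat& xh = xhat.slice(c);
    dgamma(c) = accu(g % xh);
    dbeta(c) = accu(g);
    const double n = g.n_elem;
    mat dxhat = gamma(c) * g;
    dx.slice(c) = istd(c) *
      (dxhat - accu(dxhat) / n - xh * (accu(dxhat % xh) / n));
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
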
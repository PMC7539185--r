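// Low-level kernels for the 2D convolution engine.
//
// Tensors are H x W x C arma::cubes (R arrays with dim = c(H, W, C)).
// im2col lays out patches so that column j corresponds to output pixel
// (i2, j2) in column-major order and row index runs (kh, kw, c) with kh
// fastest, matching how weight matrices are reshaped on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = out_size(H, k, stride, pad);
  const int W2 = out_size(W, k, stride, pad);
  const size_t nrow = (size_t)C * k * k;
  arma::mat col(nrow, (size_t)H2 * W2, arma::fill::zeros);
  const double* xp = x.memptr();
  double* cp = col.memptr();
  const size_t hw = (size_t)H * W;
  for (int j2 = 0; j2 < W2; ++j2) {
    const int j0 = j2 * stride - pad;
    for (int i2 = 0; i2 < H2; ++i2) {
      const int i0 = i2 * stride - pad;
      double* dst = cp + ((size_t)j2 * H2 + i2) * nrow;
      const bool interior = i0 >= 0 && j0 >= 0 && i0 + k <= H && j0 + k <= W;
      if (interior) {
        for (int c = 0; c < C; ++c) {
          const double* base = xp + c * hw + (size_t)j0 * H + i0;
          double* d2 = dst + (size_t)c * k * k;
          for (int kw = 0; kw < k; ++kw) {
            std::memcpy(d2 + (size_t)kw * k, base + (size_t)kw * H,
                        k * sizeof(double));
          }
        }
      } else {
        for (int c = 0; c < C; ++c) {
          const double* base = xp + c * hw;
          double* d2 = dst + (size_t)c * k * k;
          for (int kw = 0; kw < k; ++kw) {
            const int jj = j0 + kw;
            if (jj < 0 || jj >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int ii = i0 + kh;
              if (ii >= 0 && ii < H)
                d2[(size_t)kw * k + kh] = base[(size_t)jj * H + ii];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& col, int H, int W, int C,
                      int k, int stride, int pad) {
  const int H2 = out_size(H, k, stride, pad);
  const int W2 = out_size(W, k, stride, pad);
  const size_t nrow = (size_t)C * k * k;
  arma::cube x(H, W, C, arma::fill::zeros);
  double* xp = x.memptr();
  const double* cp = col.memptr();
  const size_t hw = (size_t)H * W;
  for (int j2 = 0; j2 < W2; ++j2) {
    const int j0 = j2 * stride - pad;
    for (int i2 = 0; i2 < H2; ++i2) {
      const int i0 = i2 * stride - pad;
      const double* src = cp + ((size_t)j2 * H2 + i2) * nrow;
      const bool interior = i0 >= 0 && j0 >= 0 && i0 + k <= H && j0 + k <= W;
      for (int c = 0; c < C; ++c) {
        double* base = xp + c * hw;
        const double* s2 = src + (size_t)c * k * k;
        for (int kw = 0; kw < k; ++kw) {
          const int jj = j0 + kw;
          if (!interior && (jj < 0 || jj >= W)) continue;
          double* dcol = base + (size_t)jj * H + i0;
          const double* scol = s2 + (size_t)kw * k;
          if (interior) {
            for (int kh = 0; kh < k; ++kh) dcol[kh] += scol[kh];
          } else {
            for (int kh = 0; kh < k; ++kh) {
              const int ii = i0 + kh;
              if (ii >= 0 && ii < H) base[(size_t)jj * H + ii] += scol[kh];
            }
          }
        }
      }
    }
  }
  return x;
}

static arma::mat im2col_internal(const arma::cube& x, int k, int stride, int pad) {
  return cpp_im2col(x, k, stride, pad);
}

// Full convolution forward: out(i2, j2, o) = sum W(o, :) col(:, pix) + b(o).
// The patch matrix lives on the C++ heap (returned as an external pointer
// for reuse in the backward pass), which keeps multi-megabyte caches away
// from the R garbage collector.
// [[Rcpp::export]]
List cpp_conv_fwd(const arma::cube& x, const arma::mat& W,
                  const arma::vec& b, int k, int stride, int pad,
                  bool keep_col) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int H2 = out_size(H, k, stride, pad);
  const int W2 = out_size(Wd, k, stride, pad);
  const int O = W.n_rows;
  arma::mat* col = new arma::mat(cpp_im2col(x, k, stride, pad));
  arma::mat out = W * (*col);            // O x npix
  out.each_col() += b;
  arma::cube res(H2, W2, O);
  double* rp = res.memptr();
  const double* op = out.memptr();
  const size_t npix = (size_t)H2 * W2;
  for (size_t p = 0; p < npix; ++p)
    for (int o = 0; o < O; ++o)
      rp[(size_t)o * npix + p] = op[p * O + o];
  if (keep_col) {
    XPtr<arma::mat> colptr(col, true);
    return List::create(_["out"] = res, _["col"] = colptr);
  }
  delete col;
  return List::create(_["out"] = res);
}

// Convolution backward from the cached patch matrix. Returns gradients with
// respect to the input, the weights and the bias.
// [[Rcpp::export]]
List cpp_conv_bwd(SEXP colptr_, const arma::mat& W, const arma::cube& gout,
                  int H, int Wd, int C, int k, int stride, int pad) {
  XPtr<arma::mat> colptr(colptr_);
  const int O = W.n_rows;
  const size_t npix = (size_t)gout.n_rows * gout.n_cols;
  arma::mat gmat(O, npix);
  const double* gp = gout.memptr();
  double* gm = gmat.memptr();
  for (size_t p = 0; p < npix; ++p)
    for (int o = 0; o < O; ++o)
      gm[p * O + o] = gp[(size_t)o * npix + p];
  arma::mat gW = gmat * colptr->t();
  arma::vec gb = arma::sum(gmat, 1);
  arma::mat gcol = W.t() * gmat;
  arma::cube gin = cpp_col2im(gcol, H, Wd, C, k, stride, pad);
  return List::create(_["gin"] = gin, _["gW"] = gW, _["gb"] = gb);
}

// Pairwise squared-distance clash scan: smallest distance between atoms
// with index separation >= min_sep. Coordinates are an L x 3 matrix.
// [[Rcpp::export]]
double cpp_min_nonadjacent_dist(const arma::mat& xyz, int min_sep) {
  const int L = xyz.n_rows;
  double best = arma::datum::inf;
  for (int i = 0; i < L; ++i) {
    for (int j = i + min_sep; j < L; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
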
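// Low-level kernels: dilated 2-D convolution (im2col + GEMM) with explicit
// backward pass, and 8-connected component labelling. Convolutions use
// same-padding; weights are passed flattened column-major from an R array of
// dim (k, k, Cin, Cout), i.e. a (k*k*Cin) x Cout matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col in (HW x k*k*Cin) orientation: column r holds the shifted image for
// one (channel, kernel-offset) pair, so each (output column j) segment is a
// contiguous run and Y = cols * W needs no transpose.
static arma::mat im2col_dil(const arma::cube& X, int k, int dil) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int off = (k - 1) / 2;
  arma::mat cols((size_t)H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Xc = X.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        const int di = (ki - off) * dil, dj = (kj - off) * dil;
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        if (i0 > i1) continue;
        double* dst = cols.colptr(r);
        for (int j = j0; j <= j1; ++j) {
          const double* src = Xc.colptr(j + dj) + (i0 + di);
          std::copy(src, src + (i1 - i0 + 1), dst + (size_t)j * H + i0);
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& X, const arma::mat& Wm,
                     const arma::vec& b, int k, int dil) {
  const int H = X.n_rows, W = X.n_cols;
  const int Cout = Wm.n_cols;
  arma::mat Ymat;
  if (k == 1) {
    // 1x1 conv is a plain channel mix; skip im2col
    arma::mat Xmat((double*)X.memptr(), (size_t)H * W, X.n_slices);
    Ymat = Xmat * Wm;  // (HW x Cout)
    Ymat.each_row() += b.t();
    arma::cube Y(Ymat.memptr(), H, W, Cout);
    return Y;
  }
  arma::mat cols = im2col_dil(X, k, dil);
  Ymat = cols * Wm;  // (HW x Cout)
  Ymat.each_row() += b.t();
  arma::cube Y(Ymat.memptr(), H, W, Cout);
  return Y;
}

// [[Rcpp::export]]
List conv2d_bw(const arma::cube& X, const arma::mat& Wm, const arma::cube& dY,
               int k, int dil) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const int Cout = dY.n_slices;
  arma::mat dYmat((double*)dY.memptr(), (size_t)H * W, Cout);
  arma::vec db = arma::sum(dYmat, 0).t();
  if (k == 1) {
    arma::mat Xmat((double*)X.memptr(), (size_t)H * W, Cin);
    arma::mat dW = Xmat.t() * dYmat;
    arma::mat dXmat = dYmat * Wm.t();
    arma::cube dX(dXmat.memptr(), H, W, Cin);
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  arma::mat cols = im2col_dil(X, k, dil);
  arma::mat dW = cols.t() * dYmat;             // (kkCin x Cout)
  arma::mat dcols = dYmat * Wm.t();            // (HW x kkCin)
  // col2im: scatter-add dcols back onto the input grid, contiguous runs
  arma::cube dX(H, W, Cin, arma::fill::zeros);
  const int off = (k - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    arma::mat& dXc = dX.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = c * k * k + kj * k + ki;
        const int di = (ki - off) * dil, dj = (kj - off) * dil;
        const int i0 = std::max(0, -di), i1 = std::min(H - 1, H - 1 - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W - 1, W - 1 - dj);
        if (i0 > i1) continue;
        const double* src = dcols.colptr(r);
        for (int j = j0; j <= j1; ++j) {
          double* dst = dXc.colptr(j + dj) + (i0 + di);
          const double* s = src + (size_t)j * H + i0;
          const int len = i1 - i0 + 1;
          for (int t = 0; t < len; ++t) dst[t] += s[t];
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// 8-connected labelling of a binary matrix; labels 1..n in first-encounter
// (column-major) order, background stays 0.
// [[Rcpp::export]]
IntegerMatrix label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(j * H + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= H || qj < 0 || qj >= W) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qj * H + qi);
            }
          }
        }
      }
    }
  }
  return lab;
}
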
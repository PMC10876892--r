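// Convolution and resampling primitives for the desk-scale staged CNN.
// Tensors are R arrays H x W x C (column-major), mapped to arma::cube with
// n_rows = H, n_cols = W, n_slices = C. Weights for a k x k conv with Cin
// input and Cout output channels arrive as a (k*k*Cin) x Cout matrix whose
// row order matches the R array w[kh, kw, cin, cout] flattening (kernel row
// fastest, then kernel col, then input channel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw, int stride,
                        int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(Ho * (arma::uword)Wo, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = di + dj * kh + c * kh * kw;
        for (int ox = 0; ox < Wo; ++ox) {
          const int xin = ox * stride - pad + dj;
          if (xin < 0 || xin >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int yin = oy * stride - pad + di;
            if (yin < 0 || yin >= H) continue;
            cols(oy + (arma::uword)ox * Ho, col) = x(yin, xin, c);
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(".conv2d_forward")]]
arma::cube conv2d_forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat y = cols * w;
  y.each_row() += b.t();
  arma::cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export(".conv2d_backward")]]
List conv2d_backward(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dy, int kh, int kw, int stride,
                     int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat dyMat(const_cast<double*>(dy.memptr()), Ho * (arma::uword)Wo,
                  Cout, false, true);
  arma::mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat dw = cols.t() * dyMat;
  arma::vec db = arma::sum(dyMat, 0).t();
  arma::mat dcols = dyMat * w.t();
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = di + dj * kh + c * kh * kw;
        for (int ox = 0; ox < Wo; ++ox) {
          const int xin = ox * stride - pad + dj;
          if (xin < 0 || xin >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int yin = oy * stride - pad + di;
            if (yin < 0 || yin >= H) continue;
            dx(yin, xin, c) += dcols(oy + (arma::uword)ox * Ho, col);
          }
        }
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export(".upsample2x_forward")]]
arma::cube upsample2x_forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(".upsample2x_backward")]]
arma::cube upsample2x_backward(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// 4-connected component labeling of a binary mask (integer matrix).
// [[Rcpp::export(".ccl_label")]]
IntegerMatrix ccl_label(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [y, x] = stack.back();
        stack.pop_back();
        const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int ny = y + dy[k], nx = x + dx[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) != 0 && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.emplace_back(ny, nx);
          }
        }
      }
    }
  }
  return lab;
}
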
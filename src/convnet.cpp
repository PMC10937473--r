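// Minimal CPU convolution kernels for the keypoint U-Net.
// Layout: images are H x W x C arma cubes (R arrays, column-major);
// conv weights are (k*k*C_in) x C_out matrices with rows ordered
// (channel, dx, dy) to match im2col() below. Same-padding, stride 1,
// kernel size 1 or 3.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = k / 2;
  mat cols(static_cast<uword>(H) * W, static_cast<uword>(k) * k * C);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        mat shifted(H, W, fill::zeros);
        int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        if (r1 > r0 && c1 > c0) {
          shifted.submat(r0, c0, r1 - 1, c1 - 1) =
            xs.submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj);
        }
        cols.col(col++) = vectorise(shifted);
      }
    }
  }
  return cols;
}

// scatter-add the columns back: adjoint of im2col
static cube col2im(const mat& dcols, int H, int W, int C, int k) {
  const int p = k / 2;
  cube dx(H, W, C, fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        mat d = reshape(dcols.col(col++), H, W);
        int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        if (r1 > r0 && c1 > c0) {
          dx.slice(c).submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj) +=
            d.submat(r0, c0, r1 - 1, c1 - 1);
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  const int K = w.n_cols;
  mat y = im2col(x, k) * w;
  y.each_row() += b.t();
  cube out(H, W, K);
  for (int c = 0; c < K; ++c) out.slice(c) = reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::mat& w,
                     const arma::cube& dy, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int K = dy.n_slices;
  mat dy_mat(static_cast<uword>(H) * W, K);
  for (int c = 0; c < K; ++c) dy_mat.col(c) = vectorise(dy.slice(c));
  mat cols = im2col(x, k);
  mat dW = cols.t() * dy_mat;
  vec db = sum(dy_mat, 0).t();
  cube dx = col2im(dy_mat * w.t(), H, W, C, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);  // winner offset 0..3: (di + 2*dj)
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bo = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bo = di + 2 * dj; }
          }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bo;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::cube maxpool2_bw(const arma::ucube& idx, const arma::cube& dy,
                       int H, int W) {
  const int C = dy.n_slices, Ho = dy.n_rows, Wo = dy.n_cols;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        int o = idx(i, j, c);
        dx(2 * i + (o % 2), 2 * j + (o / 2), c) += dy(i, j, c);
      }
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fw")]]
arma::cube upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::cube upsample2_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return dx;
}
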
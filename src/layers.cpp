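// Core dense-prediction layer kernels for the small U-Net.
// Tensors are arma::cube in (H, W, C) layout; convolution weights arrive
// flattened column-major to (k*k*C_in, C_out) so the patch ordering of
// im2col below must match R's array(k, k, C_in, C_out) flattening:
// row index = dh + k*dw + k*k*c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  mat out(k * k * C, Ho * Wo, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < k; ++dw)
      for (int dh = 0; dh < k; ++dh) {
        const int row = dh + k * dw + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j + dw - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i + dh - pad;
            if (xi < 0 || xi >= H) continue;
            out(row, i + Ho * j) = x(xi, xj, c);
          }
        }
      }
  return out;
}

// stride-1 convolution, zero padding `pad`
// [[Rcpp::export]]
arma::cube conv_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                   int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  const int Co = w.n_cols;
  mat xc = im2col(x, k, pad);
  mat y = w.t() * xc;  // (Co, Ho*Wo)
  y.each_col() += b;
  cube out(Ho, Wo, Co);
  for (int c = 0; c < Co; ++c) out.slice(c) = reshape(y.row(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                   int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols, Co = gy.n_slices;
  const int N = Ho * Wo;
  mat G(Co, N);
  for (int c = 0; c < Co; ++c) G.row(c) = reshape(gy.slice(c), 1, N);
  mat xc = im2col(x, k, pad);
  mat gw = xc * G.t();  // (k*k*C, Co)
  vec gb = sum(G, 1);
  mat gcol = w * G;     // (k*k*C, N), scatter-add back to input
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < k; ++dw)
      for (int dh = 0; dh < k; ++dh) {
        const int row = dh + k * dw + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int xj = j + dw - pad;
          if (xj < 0 || xj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int xi = i + dh - pad;
            if (xi < 0 || xi >= H) continue;
            gx(xi, xj, c) += gcol(row, i + Ho * j);
          }
        }
      }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// 2x2 max pooling, stride 2; idx records the argmax corner (0..3) per cell
// [[Rcpp::export]]
Rcpp::List maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  static const int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
  cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = x(2 * i, 2 * j, c);
        int bi = 0;
        for (int t = 1; t < 4; ++t) {
          const double v = x(2 * i + di[t], 2 * j + dj[t], c);
          if (v > best) { best = v; bi = t; }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bw(const arma::cube& gy, const arma::cube& idx) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  static const int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
  cube gx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int t = (int)idx(i, j, c);
        gx(2 * i + di[t], 2 * j + dj[t], c) = gy(i, j, c);
      }
  return gx;
}

// 2x2 transposed convolution, stride 2 (the classic U-Net "up-conv").
// Weight rows ordered di + 2*dj + 4*c_in to match array(2, 2, C_in, C_out).
// [[Rcpp::export]]
arma::cube convt2_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Co = w.n_cols, N = H * W;
  mat X(C, N);
  for (int c = 0; c < C; ++c) X.row(c) = reshape(x.slice(c), 1, N);
  cube y(2 * H, 2 * W, Co);
  for (int co = 0; co < Co; ++co) y.slice(co).fill(b(co));
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      mat Wsub(C, Co);
      for (int c = 0; c < C; ++c) Wsub.row(c) = w.row(di + 2 * dj + 4 * c);
      mat Ysub = Wsub.t() * X;  // (Co, N)
      for (int co = 0; co < Co; ++co)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            y(2 * i + di, 2 * j + dj, co) += Ysub(co, i + H * j);
    }
  return y;
}

// [[Rcpp::export]]
Rcpp::List convt2_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Co = gy.n_slices, N = H * W;
  mat X(C, N);
  for (int c = 0; c < C; ++c) X.row(c) = reshape(x.slice(c), 1, N);
  mat gw(4 * C, Co, fill::zeros);
  cube gx(H, W, C, fill::zeros);
  vec gb(Co, fill::zeros);
  for (int co = 0; co < Co; ++co) gb(co) = accu(gy.slice(co));
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      mat Gsub(Co, N);
      for (int co = 0; co < Co; ++co)
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            Gsub(co, i + H * j) = gy(2 * i + di, 2 * j + dj, co);
      mat gwsub = X * Gsub.t();  // (C, Co)
      mat Wsub(C, Co);
      for (int c = 0; c < C; ++c) {
        gw.row(di + 2 * dj + 4 * c) = gwsub.row(c);
        Wsub.row(c) = w.row(di + 2 * dj + 4 * c);
      }
      mat gxsub = Wsub * Gsub;  // (C, N)
      for (int c = 0; c < C; ++c) gx.slice(c) += reshape(gxsub.row(c), H, W);
    }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
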
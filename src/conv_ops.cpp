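// Convolution and pooling kernels for the image-like-array classifier.
//
// Batches are stored column-wise: one image per column, flattened in R's
// column-major array order, element (x, y, c) at index x + W*y + W*H*c
// (0-based).  Convolutions are 3x3, stride 1, zero ("same") padding,
// implemented as per-image im2col + BLAS gemm in single precision (the
// conventional precision for convolutional network training); max pooling
// is 2x2, stride 2, valid (floor) — odd trailing rows/columns are
// dropped.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Patch rows are laid out c*9 + (dy+1)*3 + (dx+1); weight matrices K must
// be (9*Cin) x F in the same order.  im2col works one image at a time so
// the column buffer stays cache-resident.
static void build_cols_one(const float* xp, int W, int H, int Cin,
                           arma::fmat& cols) {
  const int WH = W * H;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      float* cp = cols.colptr(y * W + x);
      for (int c = 0; c < Cin; ++c) {
        const float* plane = xp + static_cast<size_t>(WH) * c;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = x + dx;
            cp[c * 9 + (dy + 1) * 3 + (dx + 1)] =
              (xx >= 0 && xx < W && yy >= 0 && yy < H)
                ? plane[xx + W * yy] : 0.0f;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv2d_fwd(const arma::mat& X, int W, int H, int Cin,
                         const arma::mat& K, const arma::vec& b) {
  const int N = X.n_cols, WH = W * H, F = K.n_cols;
  if (static_cast<int>(X.n_rows) != WH * Cin)
    stop("conv2d: input has %d rows, expected %d", X.n_rows, WH * Cin);
  if (static_cast<int>(K.n_rows) != 9 * Cin)
    stop("conv2d: kernel has %d rows, expected %d", K.n_rows, 9 * Cin);
  const arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  const arma::fmat Kf = arma::conv_to<arma::fmat>::from(K);
  const arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
  arma::fmat cols(9 * Cin, WH);
  arma::fmat Y(static_cast<size_t>(WH) * F, N);
  arma::fmat Yn(WH, F);
  for (int n = 0; n < N; ++n) {
    build_cols_one(Xf.colptr(n), W, H, Cin, cols);
    Yn = cols.t() * Kf;                     // WH x F, output layout
    Yn.each_row() += bf;
    std::copy(Yn.memptr(), Yn.memptr() + static_cast<size_t>(WH) * F,
              Y.colptr(n));
  }
  return arma::conv_to<arma::mat>::from(Y);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::mat& X, const arma::mat& dY, int W, int H,
                    int Cin, const arma::mat& K, bool need_dx, bool need_dw) {
  const int N = X.n_cols, WH = W * H, F = K.n_cols;
  const arma::fmat dYf = arma::conv_to<arma::fmat>::from(dY);
  const arma::fmat Kf = arma::conv_to<arma::fmat>::from(K);
  arma::fmat Xf;
  if (need_dw) Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat cols(9 * Cin, WH);
  arma::fmat dK, dX;
  arma::fvec db(F, arma::fill::zeros);
  if (need_dw) dK.zeros(9 * Cin, F);
  if (need_dx) dX.set_size(static_cast<size_t>(WH) * Cin, N);
  arma::fmat dcols(9 * Cin, WH);
  for (int n = 0; n < N; ++n) {
    // dY column is already in (WH x F) layout
    const arma::fmat Gn(const_cast<float*>(dYf.colptr(n)), WH, F, false,
                        true);
    db += arma::sum(Gn, 0).t();
    if (need_dw) {
      build_cols_one(Xf.colptr(n), W, H, Cin, cols);
      dK += cols * Gn;                      // (9*Cin) x F
    }
    if (need_dx) {
      dcols = Kf * Gn.t();                  // (9*Cin) x WH
      float* xp = dX.colptr(n);
      std::fill(xp, xp + static_cast<size_t>(WH) * Cin, 0.0f);
      for (int y = 0; y < H; ++y) {
        for (int x = 0; x < W; ++x) {
          const float* cp = dcols.colptr(y * W + x);
          for (int c = 0; c < Cin; ++c) {
            float* plane = xp + static_cast<size_t>(WH) * c;
            for (int dy = -1; dy <= 1; ++dy) {
              const int yy = y + dy;
              if (yy < 0 || yy >= H) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                const int xx = x + dx;
                if (xx < 0 || xx >= W) continue;
                plane[xx + W * yy] += cp[c * 9 + (dy + 1) * 3 + (dx + 1)];
              }
            }
          }
        }
      }
    }
  }
  return List::create(
    _["dX"] = need_dx ? arma::conv_to<arma::mat>::from(dX) : arma::mat(),
    _["dK"] = need_dw ? arma::conv_to<arma::mat>::from(dK) : arma::mat(),
    _["db"] = arma::conv_to<arma::vec>::from(db));
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::mat& X, int W, int H, int C) {
  const int N = X.n_cols, Wo = W / 2, Ho = H / 2, WH = W * H;
  if (Wo < 1 || Ho < 1) stop("maxpool: spatial dims %dx%d too small", W, H);
  arma::mat Y(static_cast<size_t>(Wo) * Ho * C, N);
  arma::imat idx(static_cast<size_t>(Wo) * Ho * C, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = X.colptr(n);
    double* yp = Y.colptr(n);
    arma::sword* ip = idx.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* plane = xp + static_cast<size_t>(WH) * c;
      for (int yo = 0; yo < Ho; ++yo) {
        for (int xo = 0; xo < Wo; ++xo) {
          int best = 2 * xo + W * (2 * yo);
          double bv = plane[best];
          const int cand[3] = {2 * xo + 1 + W * (2 * yo),
                               2 * xo + W * (2 * yo + 1),
                               2 * xo + 1 + W * (2 * yo + 1)};
          for (int k = 0; k < 3; ++k)
            if (plane[cand[k]] > bv) { bv = plane[cand[k]]; best = cand[k]; }
          const size_t out = xo + static_cast<size_t>(Wo) * yo +
                             static_cast<size_t>(Wo) * Ho * c;
          yp[out] = bv;
          ip[out] = best + static_cast<size_t>(WH) * c;  // flat, 0-based
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::mat& dY, const arma::imat& idx,
                           int W, int H, int C) {
  const int N = dY.n_cols;
  arma::mat dX(static_cast<size_t>(W) * H * C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* dp = dY.colptr(n);
    const arma::sword* ip = idx.colptr(n);
    double* xp = dX.colptr(n);
    for (size_t r = 0; r < dY.n_rows; ++r) xp[ip[r]] += dp[r];
  }
  return dX;
}
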
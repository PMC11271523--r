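// Minimal strided 2-D convolution / transposed-convolution primitives used by
// the convolutional VAE. Images travel as rows of an N x (C*H*W) matrix with
// layout idx = c*H*W + x*H + y (column-major within each channel slice, the
// same order as as.vector() of an H x W R matrix).
//
// Convolution weights:  Wm (Cout x k*k*Cin),  row-in-column order kx*k + ky.
// Transposed-conv weights: Vm (Cin x k*k*Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int conv_out(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static void im2col(const double* x, int C, int H, int W, int k, int s, int p,
                   mat& cols, int Ho, int Wo) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const int col = ox * Ho + oy;
        const int ix0 = ox * s - p, iy0 = oy * s - p;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            cols(c * k * k + kx * k + ky, col) = xc[(std::size_t)ix * H + iy];
          }
        }
      }
    }
  }
}

static void col2im(const mat& cols, int C, int H, int W, int k, int s, int p,
                   double* x, int Ho, int Wo) {
  std::fill(x, x + (std::size_t)C * H * W, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * H * W;
    for (int ox = 0; ox < Wo; ++ox) {
      for (int oy = 0; oy < Ho; ++oy) {
        const int col = ox * Ho + oy;
        const int ix0 = ox * s - p, iy0 = oy * s - p;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ix0 + kx;
          if (ix < 0 || ix >= W) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = iy0 + ky;
            if (iy < 0 || iy >= H) continue;
            xc[(std::size_t)ix * H + iy] += cols(c * k * k + kx * k + ky, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& Wm,
                       const arma::vec& b, int C, int H, int W,
                       int k, int s, int p) {
  const int N = X.n_rows;
  const int Ho = conv_out(H, k, s, p), Wo = conv_out(W, k, s, p);
  const int Cout = Wm.n_rows;
  mat Y(N, (std::size_t)Cout * Ho * Wo);
  mat cols(k * k * C, Ho * Wo);
  for (int i = 0; i < N; ++i) {
    rowvec xr = X.row(i);
    im2col(xr.memptr(), C, H, W, k, s, p, cols, Ho, Wo);
    mat yt = cols.t() * Wm.t();           // (Ho*Wo) x Cout
    yt.each_row() += b.t();
    Y.row(i) = vectorise(yt).t();         // layout c*HoWo + pos
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat& X, const arma::mat& Wm,
                        const arma::mat& dY, int C, int H, int W,
                        int k, int s, int p) {
  const int N = X.n_rows;
  const int Ho = conv_out(H, k, s, p), Wo = conv_out(W, k, s, p);
  const int Cout = Wm.n_rows;
  mat dX(N, X.n_cols);
  mat dW(size(Wm), fill::zeros);
  vec db(Cout, fill::zeros);
  mat cols(k * k * C, Ho * Wo), dcols(k * k * C, Ho * Wo);
  for (int i = 0; i < N; ++i) {
    rowvec xr = X.row(i);
    im2col(xr.memptr(), C, H, W, k, s, p, cols, Ho, Wo);
    // dY row layout c*HoWo + pos -> (Ho*Wo x Cout)
    mat dyt(dY.row(i).t());
    dyt.reshape(Ho * Wo, Cout);
    dW += dyt.t() * cols.t();
    db += sum(dyt, 0).t();
    dcols = Wm.t() * dyt.t();
    rowvec dxr(X.n_cols);
    col2im(dcols, C, H, W, k, s, p, dxr.memptr(), Ho, Wo);
    dX.row(i) = dxr;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
arma::mat cpp_tconv_fwd(const arma::mat& X, const arma::mat& Vm,
                        const arma::vec& b, int Cin, int Hin, int Win,
                        int k, int s, int p, int Cout) {
  const int N = X.n_rows;
  const int Ho = (Hin - 1) * s - 2 * p + k, Wo = (Win - 1) * s - 2 * p + k;
  mat Y(N, (std::size_t)Cout * Ho * Wo);
  for (int i = 0; i < N; ++i) {
    mat xm(X.row(i).t());
    xm.reshape(Hin * Win, Cin);           // col c = channel slice
    mat cols = Vm.t() * xm.t();           // (k*k*Cout) x (Hin*Win)
    rowvec yr(Y.n_cols);
    col2im(cols, Cout, Ho, Wo, k, s, p, yr.memptr(), Hin, Win);
    mat ym(yr.t());
    ym.reshape(Ho * Wo, Cout);
    ym.each_row() += b.t();
    Y.row(i) = vectorise(ym).t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_tconv_bwd(const arma::mat& X, const arma::mat& Vm,
                         const arma::mat& dY, int Cin, int Hin, int Win,
                         int k, int s, int p, int Cout) {
  const int N = X.n_rows;
  const int Ho = (Hin - 1) * s - 2 * p + k, Wo = (Win - 1) * s - 2 * p + k;
  mat dX(N, X.n_cols);
  mat dV(size(Vm), fill::zeros);
  vec db(Cout, fill::zeros);
  mat dcols(k * k * Cout, Hin * Win);
  for (int i = 0; i < N; ++i) {
    rowvec dyr = dY.row(i);
    im2col(dyr.memptr(), Cout, Ho, Wo, k, s, p, dcols, Hin, Win);
    mat dym(dyr.t());
    dym.reshape(Ho * Wo, Cout);
    db += sum(dym, 0).t();
    mat xm(X.row(i).t());
    xm.reshape(Hin * Win, Cin);
    dV += xm.t() * dcols.t();
    mat dxm = dcols.t() * Vm.t();         // (Hin*Win) x Cin
    dX.row(i) = vectorise(dxm).t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dV") = dV,
                            Rcpp::Named("db") = db);
}
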
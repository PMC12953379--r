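// Dilated 1-D convolution kernels (same zero padding, odd kernel).
// Time along rows, channels along columns; weight array W has
// dimensions (kernel, in_channels, out_channels).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static arma::mat tap_matrix(const arma::cube& W, int j) {
  const int cin = W.n_cols, cout = W.n_slices;
  arma::mat Wj(cin, cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      Wj(ci, co) = W(j, ci, co);
  return Wj;
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
arma::mat conv1d_fwd_cpp(const arma::mat& x, const arma::cube& W,
                         const arma::vec& b, const int dilation) {
  const int n = x.n_rows, k = W.n_rows;
  const int half = (k - 1) / 2;
  arma::mat y(n, W.n_slices);
  y.each_row() = b.t();
  for (int j = 0; j < k; ++j) {
    const int o = (j - half) * dilation;
    const int lo = std::max(0, -o), hi = std::min(n - 1, n - 1 - o);
    if (lo > hi) continue;
    y.rows(lo, hi) += x.rows(lo + o, hi + o) * tap_matrix(W, j);
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(const arma::mat& x, const arma::mat& dy,
                    const arma::cube& W, const int dilation) {
  const int n = x.n_rows, k = W.n_rows;
  const int cin = W.n_cols, cout = W.n_slices;
  const int half = (k - 1) / 2;
  arma::cube dW(k, cin, cout, arma::fill::zeros);
  arma::mat dx(n, cin, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int o = (j - half) * dilation;
    const int lo = std::max(0, -o), hi = std::min(n - 1, n - 1 - o);
    if (lo > hi) continue;
    arma::mat dWj = x.rows(lo + o, hi + o).t() * dy.rows(lo, hi);
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < cin; ++ci)
        dW(j, ci, co) = dWj(ci, co);
    dx.rows(lo + o, hi + o) += dy.rows(lo, hi) * tap_matrix(W, j).t();
  }
  return List::create(_["dx"] = dx, _["dW"] = dW,
                      _["db"] = arma::sum(dy, 0).t());
}

// [[Rcpp::export(name = ".norm_time_fwd_cpp")]]
List norm_time_fwd_cpp(const arma::mat& x, const arma::vec& gamma,
                       const arma::vec& beta, const double eps) {
  const arma::rowvec mu = arma::mean(x, 0);
  arma::mat xhat = x.each_row() - mu;
  const arma::rowvec v = arma::mean(arma::square(xhat), 0);
  const arma::rowvec inv_sd = 1.0 / arma::sqrt(v + eps);
  xhat.each_row() %= inv_sd;
  arma::mat y = xhat.each_row() % gamma.t();
  y.each_row() += beta.t();
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv_sd"] = inv_sd.t());
}

// [[Rcpp::export(name = ".norm_time_bwd_cpp")]]
List norm_time_bwd_cpp(const arma::mat& dy, const arma::mat& xhat,
                       const arma::vec& inv_sd, const arma::vec& gamma) {
  const arma::rowvec dgamma = arma::sum(dy % xhat, 0);
  const arma::rowvec dbeta = arma::sum(dy, 0);
  arma::mat dxhat = dy.each_row() % gamma.t();
  const arma::rowvec m1 = arma::mean(dxhat, 0);
  const arma::rowvec m2 = arma::mean(dxhat % xhat, 0);
  arma::mat dx = dxhat.each_row() - m1;
  dx -= xhat.each_row() % m2;
  dx.each_row() %= inv_sd.t();
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma.t(),
                      _["dbeta"] = dbeta.t());
}

// [[Rcpp::export(name = ".maxpool2_fwd_cpp")]]
List maxpool2_fwd_cpp(const arma::mat& x) {
  const int n2 = x.n_rows / 2, c = x.n_cols;
  arma::mat y(n2, c);
  LogicalMatrix sel(n2, c);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < n2; ++i) {
      const double a = x(2 * i, j), b = x(2 * i + 1, j);
      const bool s = b > a;
      y(i, j) = s ? b : a;
      sel(i, j) = s;
    }
  return List::create(_["y"] = y, _["sel"] = sel);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
arma::mat maxpool2_bwd_cpp(const arma::mat& dy, const LogicalMatrix& sel) {
  const int n2 = dy.n_rows, c = dy.n_cols;
  arma::mat dx(2 * n2, c, arma::fill::zeros);
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < n2; ++i)
      dx(2 * i + (sel(i, j) ? 1 : 0), j) = dy(i, j);
  return dx;
}
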
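#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gather with implicit zero padding: idx is 1-based into x, idx == 0 reads 0.
// [[Rcpp::export]]
NumericVector gather0(const NumericVector& x, const IntegerVector& idx) {
  R_xlen_t n = idx.size();
  NumericVector out(no_init(n));
  const double* xp = x.begin();
  const int* ip = idx.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    int j = ip[i];
    op[i] = j > 0 ? xp[j - 1] : 0.0;
  }
  return out;
}

// Adjoint of gather0: scatter-add grad into a zero vector of length n.
// [[Rcpp::export]]
NumericVector scatter_add0(const NumericVector& grad, const IntegerVector& idx,
                           const double n) {
  R_xlen_t nn = (R_xlen_t)n;
  NumericVector out(nn); // zero-initialised
  R_xlen_t m = idx.size();
  const double* gp = grad.begin();
  const int* ip = idx.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    int j = ip[i];
    if (j > 0) op[j - 1] += gp[i];
  }
  return out;
}

// Convolution by kernel-offset decomposition. Activations are C x columns
// matrices where each column is the channel vector at one spatial position
// (positions image-major). For every kernel offset k the valid output
// columns o_k receive W_k (C_out x C_in) times the input columns i_k, so the
// whole convolution is a short sequence of dense GEMMs on column subsets and
// no im2col patch matrix is ever materialized.

static arma::uvec as_uvec0(const IntegerVector& v) {
  arma::uvec u(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) u[i] = (arma::uword)v[i];
  return u;
}

// [[Rcpp::export]]
arma::mat conv_forward(const arma::mat& x, const arma::mat& W, List pairs,
                       int c_in, int outcols) {
  int K = pairs.size();
  arma::mat y(W.n_rows, outcols, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    List pr = pairs[k];
    IntegerVector o = pr["o"], iv = pr["i"]; // 0-based column indices
    if (o.size() == 0) continue;
    arma::uvec ou = as_uvec0(o), iu = as_uvec0(iv);
    y.cols(ou) += W.cols(k * c_in, (k + 1) * c_in - 1) * x.cols(iu);
  }
  return y;
}

// [[Rcpp::export]]
List conv_backward(const arma::mat& x, const arma::mat& W, const arma::mat& g,
                   List pairs, int c_in, bool need_dx) {
  int K = pairs.size();
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dx;
  if (need_dx) dx.zeros(x.n_rows, x.n_cols);
  for (int k = 0; k < K; ++k) {
    List pr = pairs[k];
    IntegerVector o = pr["o"], iv = pr["i"];
    if (o.size() == 0) continue;
    arma::uvec ou = as_uvec0(o), iu = as_uvec0(iv);
    arma::mat gk = g.cols(ou);
    arma::mat xk = x.cols(iu);
    dW.cols(k * c_in, (k + 1) * c_in - 1) += gk * xk.t();
    if (need_dx) dx.cols(iu) += W.cols(k * c_in, (k + 1) * c_in - 1).t() * gk;
  }
  List out = List::create(Named("dW") = dW);
  if (need_dx) out["dx"] = dx;
  return out;
}

// ReLU forward/backward (mask recomputed from the stored output).
// [[Rcpp::export]]
arma::mat relu_forward(const arma::mat& x) {
  return arma::clamp(x, 0.0, arma::datum::inf);
}

// [[Rcpp::export]]
arma::mat relu_backward(const arma::mat& y, const arma::mat& g) {
  arma::mat dx(y.n_rows, y.n_cols);
  const double* yp = y.memptr();
  const double* gp = g.memptr();
  double* dp = dx.memptr();
  R_xlen_t n = y.n_elem;
  for (R_xlen_t i = 0; i < n; ++i) dp[i] = yp[i] > 0.0 ? gp[i] : 0.0;
  return dx;
}

// Row-wise standardization (population variance): returns the normalized
// matrix and the per-row inverse s.d. needed by the backward pass.
// [[Rcpp::export]]
List rownorm_forward(const arma::mat& x, double eps) {
  arma::vec mu = arma::mean(x, 1);
  arma::vec va = arma::mean(arma::square(x.each_col() - mu), 1);
  arma::vec inv = 1.0 / arma::sqrt(va + eps);
  arma::mat y = (x.each_col() - mu).each_col() % inv;
  return List::create(Named("y") = y, Named("inv") = inv);
}

// [[Rcpp::export]]
arma::mat rownorm_backward(const arma::mat& y, const arma::mat& g,
                           const arma::vec& inv) {
  arma::vec gm = arma::mean(g, 1);
  arma::vec gy = arma::mean(g % y, 1);
  arma::mat dx = g.each_col() - gm;
  dx -= y.each_col() % gy;
  dx.each_col() %= inv;
  return dx;
}

// FiLM modulation with per-image, per-channel scale and shift:
// y[c, col] = x[c, col] * gamma[c, img(col)] + beta[c, img(col)], where
// columns are image-major blocks of `times` spatial positions.
// [[Rcpp::export]]
arma::mat film_forward(const arma::mat& x, const arma::mat& gamma,
                       const arma::mat& beta, int times) {
  arma::uword C = x.n_rows;
  arma::mat y(C, x.n_cols);
  arma::uword n = gamma.n_cols;
  const double* xp = x.memptr();
  double* yp = y.memptr();
  for (arma::uword img = 0; img < n; ++img) {
    const double* gp = gamma.colptr(img);
    const double* bp = beta.colptr(img);
    for (arma::uword t = 0; t < (arma::uword)times; ++t) {
      arma::uword off = (img * times + t) * C;
      for (arma::uword c = 0; c < C; ++c)
        yp[off + c] = xp[off + c] * gp[c] + bp[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List film_backward(const arma::mat& x, const arma::mat& gamma,
                   const arma::mat& g, int times) {
  arma::uword C = x.n_rows;
  arma::uword n = gamma.n_cols;
  arma::mat dx(C, x.n_cols);
  arma::mat dgamma(C, n, arma::fill::zeros), dbeta(C, n, arma::fill::zeros);
  const double* xp = x.memptr();
  const double* gp = g.memptr();
  double* dxp = dx.memptr();
  for (arma::uword img = 0; img < n; ++img) {
    const double* ga = gamma.colptr(img);
    double* dg = dgamma.colptr(img);
    double* db = dbeta.colptr(img);
    for (arma::uword t = 0; t < (arma::uword)times; ++t) {
      arma::uword off = (img * times + t) * C;
      for (arma::uword c = 0; c < C; ++c) {
        dxp[off + c] = gp[off + c] * ga[c];
        dg[c] += gp[off + c] * xp[off + c];
        db[c] += gp[off + c];
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
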
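// im2col convolution kernels. Activations are (features x batch)
// matrices; `idx` is the precomputed 1-based im2col index map
// (positions x kernel elements) built once per layer in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward pass: returns the (positions * filters) x batch output matrix.
// [[Rcpp::export(".conv_fwd_cpp")]]
arma::mat conv_fwd_cpp(const arma::mat& X, const IntegerMatrix& idx,
                       const arma::mat& W, const arma::vec& bias) {
  const int P = idx.nrow(), K = idx.ncol(), B = X.n_cols, F = W.n_cols;
  arma::mat out(P * F, B);
  arma::mat M(P, K);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    for (int k = 0; k < K; ++k) {
      double* mk = M.colptr(k);
      const int* ik = &idx(0, k);
      for (int p = 0; p < P; ++p) mk[p] = xb[ik[p] - 1];
    }
    arma::mat Z = M * W;  // P x F
    Z.each_row() += bias.t();
    std::memcpy(out.colptr(b), Z.memptr(), sizeof(double) * P * F);
  }
  return out;
}

// Backward pass: gradients w.r.t. input, weights and bias.
// dY is (positions * filters) x batch.
// [[Rcpp::export(".conv_bwd_cpp")]]
List conv_bwd_cpp(const arma::mat& X, const IntegerMatrix& idx,
                  const arma::mat& W, const arma::mat& dY) {
  const int P = idx.nrow(), K = idx.ncol(), B = X.n_cols, F = W.n_cols;
  const int n_in = X.n_rows;
  arma::mat dX(n_in, B, arma::fill::zeros);
  arma::mat dW(K, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat M(P, K);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.colptr(b);
    for (int k = 0; k < K; ++k) {
      double* mk = M.colptr(k);
      const int* ik = &idx(0, k);
      for (int p = 0; p < P; ++p) mk[p] = xb[ik[p] - 1];
    }
    const arma::mat dZ(const_cast<double*>(dY.colptr(b)), P, F, false, true);
    dW += M.t() * dZ;
    db += arma::sum(dZ, 0).t();
    arma::mat dM = dZ * W.t();  // P x K
    double* dxb = dX.colptr(b);
    for (int k = 0; k < K; ++k) {
      const double* dmk = dM.colptr(k);
      const int* ik = &idx(0, k);
      for (int p = 0; p < P; ++p) dxb[ik[p] - 1] += dmk[p];
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
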
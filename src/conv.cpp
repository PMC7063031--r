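// Time-axis convolution kernels for the channel-independent ConvNet.
//
// Activations are matrices of shape (n_seq * T) x maps, rows ordered
// sequence-fastest, time-slowest. A "valid" convolution with kernel
// width K is then a sum of K shifted matrix products, which avoids
// materialising the K-fold im2col expansion:
//   out = sum_k A[rows k*n .. k*n + n*t_out - 1, ] * W_k
// with W stored as a (m_in * K) x m_out matrix whose k-th row block is
// W_k (input-map index fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& A, const arma::mat& Wm,
                       const int n, const int T, const int K) {
  const int t_out = T - K + 1;
  const int m_in = A.n_cols;
  mat out(n * t_out, Wm.n_cols, fill::zeros);
  for (int k = 0; k < K; ++k) {
    out += A.rows(k * n, k * n + n * t_out - 1) *
           Wm.rows(k * m_in, (k + 1) * m_in - 1);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv_bwd_cpp(const arma::mat& A, const arma::mat& Wm,
                        const arma::mat& dZ, const int n, const int T,
                        const int K) {
  const int t_out = T - K + 1;
  const int m_in = A.n_cols;
  mat dW(Wm.n_rows, Wm.n_cols, fill::zeros);
  mat dA(A.n_rows, m_in, fill::zeros);
  for (int k = 0; k < K; ++k) {
    dW.rows(k * m_in, (k + 1) * m_in - 1) =
        A.rows(k * n, k * n + n * t_out - 1).t() * dZ;
    dA.rows(k * n, k * n + n * t_out - 1) +=
        dZ * Wm.rows(k * m_in, (k + 1) * m_in - 1).t();
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA, Rcpp::Named("dW") = dW);
}
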
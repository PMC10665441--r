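// Symmetric (parallel-extraction) FastICA inner loop with the log-cosh
// contrast, operating on pre-whitened data. Kept in compiled code because an
// ensemble run performs thousands of fixed-point fits.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// W <- (W W^T)^{-1/2} W, the symmetric decorrelation step
static mat sym_decorrelate(const mat& W) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, W * W.t());
  return evec * diagmat(1.0 / sqrt(eval)) * evec.t() * W;
}

// [[Rcpp::export(name = ".fastica_sym")]]
Rcpp::List fastica_sym(const arma::mat& Z, const arma::mat& W0,
                       double tol, int max_iter, double alpha) {
  const double n = static_cast<double>(Z.n_cols);
  mat W = sym_decorrelate(W0);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    mat G = tanh(alpha * (W * Z));
    vec g1_mean = alpha * (1.0 - mean(square(G), 1));
    mat W1 = sym_decorrelate((G * Z.t()) / n - diagmat(g1_mean) * W);
    double lim = abs(abs(diagvec(W1 * W.t())) - 1.0).max();
    W = W1;
    if (lim < tol) {
      converged = true;
      break;
    }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("iter") = it,
                            Rcpp::Named("converged") = converged);
}
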
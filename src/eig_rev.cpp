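// Eigendecomposition of a time-reversible rate matrix via similarity to a
// symmetric matrix: B = D Q D^{-1} with D = diag(sqrt(pi)) is symmetric when
// pi Q satisfies detailed balance, so Q = U diag(lambda) Uinv with
// U = D^{-1} V, Uinv = V^T D and B = V diag(lambda) V^T.
// This is the hot path of likelihood optimisation and quadrature (one call
// per (kappa, omega) evaluation), hence compiled.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export(name = ".eig_rev_cpp")]]
Rcpp::List eig_rev_cpp(const arma::mat& Q, const arma::vec& pi) {
  const arma::uword k = Q.n_rows;
  arma::vec s = arma::sqrt(pi);
  arma::mat B(k, k);
  for (arma::uword j = 0; j < k; j++)
    for (arma::uword i = 0; i < k; i++)
      B(i, j) = Q(i, j) * s(i) / s(j);
  B = 0.5 * (B + B.t());  // symmetrise round-off
  arma::vec lambda;
  arma::mat V;
  bool ok = arma::eig_sym(lambda, V, B);
  if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);
  arma::mat U = V.each_col() / s;
  arma::mat Uinv = V.t();
  Uinv.each_row() %= s.t();
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("lambda") = lambda,
                            Rcpp::Named("U") = U,
                            Rcpp::Named("Uinv") = Uinv);
}
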
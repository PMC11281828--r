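// Fused numerical kernels for the attention heads — the dominant cost of a
// training step (two blocks x eight heads of n x n score matrices). Forward
// returns the row-stochastic attention matrix alongside the head output so
// the backward pass can reuse it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".attnHeadForward")]]
Rcpp::List attnHeadForward(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                           const bool scaled) {
  mat S = Q * K.t();
  if (scaled) S /= std::sqrt((double) Q.n_cols);
  vec rmax = max(S, 1);
  S.each_col() -= rmax;
  mat a = exp(S);
  a.each_col() /= sum(a, 1);
  mat out = a * V;
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("a") = a);
}

// [[Rcpp::export(name = ".attnHeadBackward")]]
Rcpp::List attnHeadBackward(const arma::mat& a, const arma::mat& Q, const arma::mat& K,
                            const arma::mat& V, const arma::mat& g, const bool scaled) {
  mat ga = g * V.t();
  mat gV = a.t() * g;
  mat gS = (ga - repmat(sum(ga % a, 1), 1, a.n_cols)) % a;
  if (scaled) gS /= std::sqrt((double) Q.n_cols);
  mat gQ = gS * K;
  mat gK = gS.t() * Q;
  return Rcpp::List::create(Rcpp::Named("gQ") = gQ, Rcpp::Named("gK") = gK,
                            Rcpp::Named("gV") = gV);
}
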
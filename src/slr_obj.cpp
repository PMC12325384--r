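#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Penalized negative log-likelihood of multinomial logistic regression.
// wvec: (p1*K) weights column-major; X1: n x p1 design (bias included);
// yi: 1-based class index per row; alpha: p1 ridge precisions (bias first).
// [[Rcpp::export]]
double slr_negobj(const arma::vec& wvec, const arma::mat& X1,
                  const arma::uvec& yi, const arma::vec& alpha, int K) {
  const uword p1 = X1.n_cols, n = X1.n_rows;
  mat W(const_cast<double*>(wvec.memptr()), p1, K, false, true);
  mat Z = X1 * W;
  vec zmax = max(Z, 1);
  Z.each_col() -= zmax;
  vec lse = zmax + log(sum(exp(Z), 1));
  double ll = 0.0;
  for (uword i = 0; i < n; ++i) ll += Z(i, yi(i) - 1) + zmax(i) - lse(i);
  mat W2 = W % W;
  double pen = 0.5 * dot(alpha, sum(W2, 1));
  return -ll + pen;
}

// Gradient of slr_negobj with respect to wvec.
// [[Rcpp::export]]
arma::vec slr_neggrad(const arma::vec& wvec, const arma::mat& X1,
                      const arma::uvec& yi, const arma::vec& alpha, int K) {
  const uword p1 = X1.n_cols, n = X1.n_rows;
  mat W(const_cast<double*>(wvec.memptr()), p1, K, false, true);
  mat Z = X1 * W;
  vec zmax = max(Z, 1);
  Z.each_col() -= zmax;
  mat P = exp(Z);
  P.each_col() /= sum(P, 1);
  for (uword i = 0; i < n; ++i) P(i, yi(i) - 1) -= 1.0;
  mat G = X1.t() * P;      // p1 x K likelihood part
  mat pen = W;
  pen.each_col() %= alpha; // ridge part: alpha_f * w_fk
  G += pen;
  return vectorise(G);
}
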
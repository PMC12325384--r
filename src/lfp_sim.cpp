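#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Adds one band's oscillation to the LFP matrix in place.
// x: sites x samples; phi: latent band phase per sample; eta_knots: per-site
// phase wander at uniform knots (knot_ms apart, 1 kHz samples); bump_col:
// 1-based column into bumps while a tone is on, 0 during silence; bumps:
// sites x frequencies tonotopic gains in [0,1].
// [[Rcpp::export]]
void lfp_add_band(Rcpp::NumericMatrix x, const arma::vec& phi,
                  const arma::mat& eta_knots, double knot_ms,
                  const arma::ivec& bump_col, const arma::mat& bumps,
                  double amp, double contrast) {
  const int S = x.nrow(), n = x.ncol();
  const int nk = eta_knots.n_cols;
  for (int j = 0; j < n; ++j) {
    double tk = j / knot_ms;
    int i0 = std::min((int)tk, nk - 2);
    double frac = tk - i0;
    int col = bump_col[j];
    for (int s = 0; s < S; ++s) {
      double eta = eta_knots(s, i0) * (1.0 - frac) + eta_knots(s, i0 + 1) * frac;
      double gain = (col > 0) ? 1.0 + contrast * bumps(s, col - 1) : 1.0;
      x(s, j) += amp * gain * std::cos(phi[j] + eta);
    }
  }
}
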
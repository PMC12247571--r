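#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// All-pairs two-dipole maps from the Gram matrices G = H' C^-1 H and
// G2 = H' C^-2 H, using the closed forms of the identity-gain pair filter:
// the 2x2 pair source CSD is inv([g_ii g_ij; g_ji g_jj]), so
//   cross = -g_ij / det,  p1 = g_jj / det,  p2 = g_ii / det,
//   coh   = |g_ij| / sqrt(g_ii g_jj),
// and the Hermitian inner product of the two filter rows is
//   (g_ii g_jj G2_ij + g_ij^2 conj(G2_ij)
//      - g_ij (g_jj G2_ii + g_ii G2_jj)) / det^2.
// Pairs failing the collinearity guard (normalized Gram condition), the
// minimum-distance rule, or dipole validity are marked invalid (NaN).
//
// Returns: coh, abs_cross, abs_inner, sqrt_p (sqrt(p1*p2)), valid.
// [[Rcpp::export(name = ".dual_pair_maps")]]
List dual_pair_maps(const arma::cx_mat& G, const arma::cx_mat& G2,
                    const LogicalVector& valid_dipole,
                    const arma::mat& dist, double min_distance,
                    double cond_guard) {
  const arma::uword m = G.n_rows;
  arma::mat coh(m, m), absc(m, m), absi(m, m), sqp(m, m);
  coh.fill(arma::datum::nan);
  absc.fill(arma::datum::nan);
  absi.fill(arma::datum::nan);
  sqp.fill(arma::datum::nan);
  LogicalMatrix valid(m, m);
  arma::vec gii = arma::real(G.diag());
  arma::vec g2ii = arma::real(G2.diag());
  const double corr_cut = (cond_guard - 1.0) / (cond_guard + 1.0);
  const double c2 = corr_cut * corr_cut;
  const double dmin = min_distance * (1.0 - 1e-9);
  for (arma::uword j = 0; j < m; ++j) {
    const bool vj = valid_dipole[j];
    const double gj = gii[j];
    for (arma::uword i = 0; i < m; ++i) {
      if (i == j || !vj || !valid_dipole[i]) continue;
      const double gi = gii[i];
      if (gi <= 0.0 || gj <= 0.0) continue;
      if (dist(i, j) < dmin) continue;
      const std::complex<double> gij = G(i, j);
      const double a2 = std::norm(gij);
      const double gg = gi * gj;
      const double det = gg - a2;
      if (det <= 0.0 || a2 > c2 * gg) continue;
      const double d2 = det * det;
      const std::complex<double> G2ij = G2(i, j);
      const std::complex<double> inner =
        (gg * G2ij + gij * gij * std::conj(G2ij)
           - gij * (gj * g2ii[i] + gi * g2ii[j])) / d2;
      coh(i, j) = std::sqrt(a2 / gg);
      absc(i, j) = std::sqrt(a2) / det;
      absi(i, j) = std::abs(inner);
      sqp(i, j) = std::sqrt(gg) / det;
      valid(i, j) = true;
    }
  }
  return List::create(_["coh"] = coh, _["abs_cross"] = absc,
                      _["abs_inner"] = absi, _["sqrt_p"] = sqp,
                      _["valid"] = valid);
}
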
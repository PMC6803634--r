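// Closed-form pulse average of the excited-singlet population under a
// rectangular excitation pulse, from the eigendecomposition of the 6x6
// kinetic generator. Hot path of the TRAST curve simulator and the global
// fitter; mirrors the R fallback in trast.R exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static std::complex<double> phi1(const std::complex<double>& z) {
  if (std::abs(z) < 1e-8) return std::complex<double>(1.0, 0.0);
  return (std::exp(z) - 1.0) / z;
}

// [[Rcpp::export(name = ".pulseAvgSingletCpp")]]
Rcpp::NumericVector pulseAvgSingletCpp(const arma::mat& M,
                                       const arma::vec& w) {
  arma::cx_vec eigval;
  arma::cx_mat eigvec;
  if (!arma::eig_gen(eigval, eigvec, M))
    return Rcpp::NumericVector(0); // caller falls back to dense propagation
  const double k01 = M(1, 0);
  const double kS = -M(1, 1);
  const double pS = (k01 + kS) > 0 ? k01 / (k01 + kS) : 0.0;
  arma::cx_vec p0(6, arma::fill::zeros);
  p0(0) = 1.0 - pS;
  p0(1) = pS;
  arma::cx_vec alpha;
  if (!arma::solve(alpha, eigvec, p0))
    return Rcpp::NumericVector(0);
  const arma::cx_rowvec row1 = eigvec.row(1);
  Rcpp::NumericVector out(w.n_elem);
  for (arma::uword i = 0; i < w.n_elem; ++i) {
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword m = 0; m < 6; ++m)
      acc += row1(m) * alpha(m) * phi1(eigval(m) * w(i));
    out[i] = acc.real();
    if (!std::isfinite(out[i])) return Rcpp::NumericVector(0);
  }
  return out;
}
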
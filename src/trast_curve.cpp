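// Shell-averaged TRAST signal: builds the 6x6 generator per beam shell and
// accumulates the CEF-weighted pulse average of the singlet population.
// Same kinetics as buildRateMatrix() + .pulseAvgSinglet() in R/.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static std::complex<double> phi1c(const std::complex<double>& z) {
  if (std::abs(z) < 1e-8) return std::complex<double>(1.0, 0.0);
  return (std::exp(z) - 1.0) / z;
}

// rates: k10, kisc, kee, kT, kred, kdeprot, fRadial, krecRadial, krecAxial
// [[Rcpp::export(name = ".trastShellSumCpp")]]
Rcpp::NumericVector trastShellSumCpp(const arma::vec& rates,
                                     bool eeFromSinglet,
                                     const arma::vec& k01s,
                                     const arma::vec& keeScales,
                                     const arma::vec& weights,
                                     const arma::vec& w) {
  const double k10 = rates(0), kisc = rates(1), keeNom = rates(2),
               kT = rates(3), kred = rates(4), kdeprot = rates(5),
               fRad = rates(6), krecR = rates(7), krecA = rates(8);
  Rcpp::NumericVector F(w.n_elem);
  arma::mat M(6, 6);
  for (arma::uword s = 0; s < k01s.n_elem; ++s) {
    const double k01 = k01s(s);
    const double kee = keeNom * keeScales(s);
    M.zeros();
    M(1, 0) = k01;
    M(0, 1) = k10;
    M(2, 1) = kisc;
    if (eeFromSinglet) M(3, 1) = kee; else M(3, 2) = kee;
    M(0, 2) = kT;
    M(0, 3) = kred;
    M(4, 3) = fRad * kdeprot;
    M(5, 3) = (1.0 - fRad) * kdeprot;
    M(0, 4) = krecR;
    M(0, 5) = krecA;
    for (int j = 0; j < 6; ++j) M(j, j) = -arma::accu(M.col(j));
    arma::cx_vec eigval;
    arma::cx_mat eigvec;
    if (!arma::eig_gen(eigval, eigvec, M))
      return Rcpp::NumericVector(0); // R fallback
    const double kS = -M(1, 1);
    const double pS = (k01 + kS) > 0 ? k01 / (k01 + kS) : 0.0;
    arma::cx_vec p0(6, arma::fill::zeros);
    p0(0) = 1.0 - pS;
    p0(1) = pS;
    arma::cx_vec alpha;
    if (!arma::solve(alpha, eigvec, p0)) return Rcpp::NumericVector(0);
    for (arma::uword i = 0; i < w.n_elem; ++i) {
      std::complex<double> acc(0.0, 0.0);
      for (arma::uword m = 0; m < 6; ++m)
        acc += eigvec(1, m) * alpha(m) * phi1c(eigval(m) * w(i));
      const double v = acc.real();
      if (!std::isfinite(v)) return Rcpp::NumericVector(0);
      F[i] += weights(s) * v;
    }
  }
  return F;
}
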
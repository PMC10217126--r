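// Direct MoM solve on the contrast support: assembles
//   A = I - C_supp * diag(chi)
// from the Toeplitz coefficient table and LU-solves for all transmitters.
// Optionally runs in single precision (cgesv), adequate for bulk database
// simulation where the result feeds a float network or is noise-corrupted;
// property tests use the double path.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
arma::cx_mat mom_support_solve(const arma::cx_mat& ctable,
                               const arma::ivec& pi, const arma::ivec& pj,
                               const arma::cx_vec& chi, const arma::cx_mat& Ei,
                               bool use_float = false) {
  const int ns = pi.n_elem;
  if (use_float) {
    arma::cx_fmat A(ns, ns);
    arma::cx_fvec chif = arma::conv_to<arma::cx_fvec>::from(chi);
    for (int q = 0; q < ns; ++q) {
      const int iq = pi[q], jq = pj[q];
      const std::complex<float> cq = chif[q];
      for (int m = 0; m < ns; ++m) {
        A.at(m, q) = -std::complex<float>(
          ctable.at(std::abs(pi[m] - iq), std::abs(pj[m] - jq))) * cq;
      }
      A.at(q, q) += 1.0f;
    }
    arma::cx_fmat Ef = arma::conv_to<arma::cx_fmat>::from(Ei);
    arma::cx_fmat X = arma::solve(A, Ef);
    return arma::conv_to<arma::cx_mat>::from(X);
  }
  arma::cx_mat A(ns, ns);
  for (int q = 0; q < ns; ++q) {
    const int iq = pi[q], jq = pj[q];
    const std::complex<double> cq = chi[q];
    for (int m = 0; m < ns; ++m)
      A.at(m, q) = -ctable.at(std::abs(pi[m] - iq), std::abs(pj[m] - jq)) * cq;
    A.at(q, q) += 1.0;
  }
  return arma::solve(A, Ei);
}
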
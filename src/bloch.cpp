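// Numerical core: kinematical structure-factor sums and Bloch-wave
// eigen-propagation of beam intensities. Conventions (documented in the
// methods vignette): structure matrix A with A_gg = 2 K S_g and
// A_gh = U_{g-h}; A Hermitian (elastic scattering only, real potential);
// wave amplitude psi_g(t) = sum_j C_gj exp(i pi gamma_j t / Kn) conj(C_0j)
// with Kn the beam-normal component of the wavevector (normal incidence on
// a parallel-sided block: Kn = K).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Structure factors F_h = sum_j occ_j f_j(s) exp(-8 pi^2 U_j s^2)
// exp(2 pi i h.r_j) over symmetry-expanded (isotropic) sites.
// elem: 1-based row index into the 5-Gaussian coefficient matrices.
// [[Rcpp::export]]
arma::cx_vec cpp_structure_factors(const arma::imat& hkl,
                                   const arma::vec& svals,
                                   const arma::mat& frac,
                                   const arma::vec& occ,
                                   const arma::vec& uiso,
                                   const arma::ivec& elem,
                                   const arma::mat& acoef,
                                   const arma::mat& bcoef) {
  const arma::uword m = hkl.n_rows, n = frac.n_rows;
  arma::cx_vec F(m, arma::fill::zeros);
  const double twopi = 2.0 * M_PI;
  for (arma::uword r = 0; r < m; ++r) {
    const double s2 = svals(r) * svals(r);
    const double h0 = hkl(r, 0), h1 = hkl(r, 1), h2 = hkl(r, 2);
    std::complex<double> acc(0.0, 0.0);
    for (arma::uword j = 0; j < n; ++j) {
      const arma::uword e = elem(j) - 1;
      double f = 0.0;
      for (int k = 0; k < 5; ++k)
        f += acoef(e, k) * std::exp(-bcoef(e, k) * s2);
      const double dw = std::exp(-8.0 * M_PI * M_PI * uiso(j) * s2);
      const double ph = twopi * (h0 * frac(j, 0) + h1 * frac(j, 1) + h2 * frac(j, 2));
      acc += occ(j) * f * dw * std::complex<double>(std::cos(ph), std::sin(ph));
    }
    F(r) = acc;
  }
  return F;
}

// Propagate a single orientation: structure matrix with off-diagonal part
// Aoff (Hermitian, zero diagonal), diagonal 2*K*S. Returns intensities of
// all beams for each thickness (n_beams x n_t).
// [[Rcpp::export]]
arma::mat cpp_propagate(const arma::cx_mat& Aoff,
                        const arma::vec& svec,
                        const arma::vec& tvec,
                        const double K) {
  arma::cx_mat A = Aoff;
  A.diag() = arma::cx_vec(2.0 * K * svec, arma::zeros(svec.n_elem));
  A = 0.5 * (A + A.t());  // enforce exact Hermiticity
  arma::vec eigval;
  arma::cx_mat eigvec;
  if (!arma::eig_sym(eigval, eigvec, A, "std"))
    stop("Bloch eigen-solver failed (n = %d beams)", (int)A.n_rows);
  const arma::uword n = A.n_rows, nt = tvec.n_elem;
  arma::cx_vec c0 = arma::conj(eigvec.row(0).t());  // entrance boundary: beam 000
  arma::mat out(n, nt);
  for (arma::uword it = 0; it < nt; ++it) {
    arma::cx_vec phase(n);
    for (arma::uword j = 0; j < n; ++j) {
      const double arg = M_PI * eigval(j) * tvec(it) / K;
      phase(j) = std::complex<double>(std::cos(arg), std::sin(arg));
    }
    arma::cx_vec psi = eigvec * (phase % c0);
    out.col(it) = arma::square(arma::abs(psi));
  }
  return out;
}

// Rocking curves for a set of reflection passes. Each pass is a list with
//   idx:  n x n integer matrix, 1-based index into U for g_i - g_j (i != j)
//   smat: n x p excitation errors per beam per grid node
//   target: 1-based row of the reflection whose intensity is wanted
// U: potential coefficients (A^-2) for the unique difference vectors.
// Returns a list of p x n_t intensity matrices (one per pass).
// [[Rcpp::export]]
List cpp_bloch_curves(const List& passes,
                      const arma::cx_vec& U,
                      const arma::vec& tvec,
                      const double K) {
  const int np = passes.size();
  List out(np);
  for (int ip = 0; ip < np; ++ip) {
    List ps = passes[ip];
    arma::imat idx = as<arma::imat>(ps["idx"]);
    arma::mat smat = as<arma::mat>(ps["smat"]);
    const int target = as<int>(ps["target"]) - 1;
    const arma::uword n = idx.n_rows, p = smat.n_cols, nt = tvec.n_elem;
    arma::cx_mat Aoff(n, n, arma::fill::zeros);
    for (arma::uword i = 1; i < n; ++i)
      for (arma::uword j = 0; j < i; ++j) {
        const std::complex<double> u = U(idx(i, j) - 1);
        Aoff(i, j) = u;
        Aoff(j, i) = std::conj(u);
      }
    arma::mat curves(p, nt);
    arma::vec eigval;
    arma::cx_mat eigvec;
    arma::cx_mat A(n, n);
    for (arma::uword c = 0; c < p; ++c) {
      A = Aoff;
      for (arma::uword i = 0; i < n; ++i) A(i, i) = 2.0 * K * smat(i, c);
      if (!arma::eig_sym(eigval, eigvec, A, "std"))
        stop("Bloch eigen-solver failed in pass %d (n = %d beams)", ip + 1, (int)n);
      arma::cx_rowvec ct = eigvec.row(target);
      arma::cx_rowvec c0 = arma::conj(eigvec.row(0));
      for (arma::uword it = 0; it < nt; ++it) {
        std::complex<double> psi(0.0, 0.0);
        for (arma::uword j = 0; j < n; ++j) {
          const double arg = M_PI * eigval(j) * tvec(it) / K;
          psi += ct(j) * c0(j) * std::complex<double>(std::cos(arg), std::sin(arg));
        }
        curves(c, it) = std::norm(psi);
      }
    }
    out[ip] = curves;
  }
  return out;
}
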
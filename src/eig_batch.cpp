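// Batched small-matrix eigenvalue kernels for the BSR objective functions.
// Matrices arrive as cubes (n x n x m); each slice is one Jacobian (or its
// symmetrization). Sizes are tiny (2-10), counts are large (1e5-1e7), so the
// win is amortizing the R call overhead, not the per-matrix solve.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Largest eigenvalue of each symmetric slice.
// [[Rcpp::export]]
arma::vec max_eig_sym_batch(const arma::cube& M) {
  const arma::uword m = M.n_slices;
  arma::vec out(m);
  arma::vec ev;
  for (arma::uword i = 0; i < m; ++i) {
    if (!M.slice(i).is_finite()) { out[i] = arma::datum::inf; continue; }
    if (arma::eig_sym(ev, M.slice(i)))
      out[i] = ev.max();
    else
      out[i] = arma::datum::inf;
  }
  return out;
}

// Largest real part among eigenvalues with |Re| > zero_tol, per slice.
// Slices with no such eigenvalue give NaN (caller decides the convention).
// [[Rcpp::export]]
arma::vec max_re_eig_nonzero_batch(const arma::cube& A, const double zero_tol) {
  const arma::uword m = A.n_slices;
  arma::vec out(m);
  arma::cx_vec ev;
  for (arma::uword i = 0; i < m; ++i) {
    if (!A.slice(i).is_finite()) { out[i] = arma::datum::inf; continue; }
    if (!arma::eig_gen(ev, A.slice(i))) { out[i] = arma::datum::inf; continue; }
    double best = arma::datum::nan;
    for (arma::uword k = 0; k < ev.n_elem; ++k) {
      const double re = ev[k].real();
      if (std::abs(re) > zero_tol && (std::isnan(best) || re > best)) best = re;
    }
    out[i] = best;
  }
  return out;
}

// Largest real part over all eigenvalues, per slice (no zero exclusion).
// [[Rcpp::export]]
arma::vec max_re_eig_batch(const arma::cube& A) {
  const arma::uword m = A.n_slices;
  arma::vec out(m);
  arma::cx_vec ev;
  for (arma::uword i = 0; i < m; ++i) {
    if (!A.slice(i).is_finite()) { out[i] = arma::datum::inf; continue; }
    if (!arma::eig_gen(ev, A.slice(i))) { out[i] = arma::datum::inf; continue; }
    out[i] = arma::real(ev).max();
  }
  return out;
}
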
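// Schur-based (Bartels-Stewart) Lyapunov solves via LAPACK dtrsyl; robust
// for defective matrices (e.g. augmented loop systems with repeated lag
// eigenvalues), where eigendecomposition-based solvers break down.

#include <RcppArmadillo.h>
#define USE_FC_LEN_T
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve T' X + X T = C_in (trans = true) or T X + X T' = C_in (false),
// with T quasi-upper-triangular (real Schur form).
static mat trsyl_solve(const mat& T, const mat& C_in, bool trans) {
  int m = T.n_rows, n = T.n_cols, info = 0, isgn = 1;
  double scale = 1.0;
  mat X = C_in;
  const char* ta = trans ? "T" : "N";
  const char* tb = trans ? "N" : "T";
  F77_CALL(dtrsyl)(ta, tb, &isgn, &m, &n, T.memptr(), &m, T.memptr(), &m,
                   X.memptr(), &m, &scale, &info FCONE FCONE);
  if (info < 0) Rcpp::stop("dtrsyl: illegal argument %d", -info);
  return X / scale;
}

// [[Rcpp::export]]
Rcpp::List lyap_pair_cpp(const arma::mat& A, const arma::mat& Cq,
                         const arma::mat& Cs, bool want_s) {
  // P solves A' P + P A + Cq = 0; S solves A S + S A' + Cs = 0.
  // One real Schur decomposition of A serves both equations.
  mat U, T;
  if (!schur(U, T, A)) Rcpp::stop("lyap_pair_cpp: Schur decomposition failed");
  mat Cqh = U.t() * Cq * U;
  mat Pt = trsyl_solve(T, -Cqh, true);
  mat P = U * Pt * U.t();
  P = 0.5 * (P + P.t());
  if (!want_s) {
    return Rcpp::List::create(Rcpp::Named("P") = P);
  }
  mat Csh = U.t() * Cs * U;
  mat St = trsyl_solve(T, -Csh, false);
  mat S = U * St * U.t();
  S = 0.5 * (S + S.t());
  return Rcpp::List::create(Rcpp::Named("P") = P, Rcpp::Named("S") = S);
}
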
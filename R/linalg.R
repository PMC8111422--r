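#' Spectral abscissa
#'
#' Largest real part of the eigenvalues of a square matrix.
#'
#' @param M square numeric matrix.
#' @return scalar, \code{max(Re(eigen(M)))}.
#' @export
spectral_abscissa <- function(M) {
  max(Re(eigen(M, only.values = TRUE)$values))
}

## Eigendecomposition cache for repeated shifted Lyapunov solves against the
## same matrix (the stabilizer solves many shifts of one W per iteration).
eigen_factor <- function(A) {
  e <- eigen(A)
  Vi <- solve(e$vectors)
  list(values = e$values, V = e$vectors, Vi = Vi)
}

#' Solve the continuous-time Lyapunov equation
#'
#' Solves \eqn{A^T X + X A + C = 0} for dense, diagonalizable \eqn{A} via the
#' eigendecomposition \eqn{A = V \Lambda V^{-1}}: in transformed coordinates
#' the solution is elementwise, \eqn{\tilde X_{ij} = -(V^T C V)_{ij} /
#' (\lambda_i + \lambda_j)}.
#'
#' @param A square matrix with no pair of eigenvalues summing to zero
#'   (e.g. Hurwitz-stable).
#' @param C symmetric right-hand side.
#' @param fac optional precomputed \code{eigen_factor(A)}.
#' @param check if \code{TRUE}, error when the relative residual exceeds
#'   \code{tol}.
#' @param tol relative residual tolerance.
#' @return symmetric solution matrix \code{X}.
#' @export
lyap_solve <- function(A, C, fac = NULL, check = TRUE, tol = 1e-7) {
  if (is.null(fac)) fac <- eigen_factor(A)
  lam <- fac$values
  den <- outer(lam, lam, `+`)
  if (min(Mod(den)) < 1e-12) {
    stop("lyap_solve: eigenvalue pair sums to ~0; equation is singular ",
         "(matrix not Hurwitz?)")
  }
  ## A^T = V^{-T} Lambda V^T ; set X = V^{-T} Xt V^{-1}
  Ct <- t(fac$V) %*% C %*% fac$V
  Xt <- -Ct / den
  X <- t(fac$Vi) %*% Xt %*% fac$Vi
  X <- Re(X)
  X <- (X + t(X)) / 2
  if (check) {
    res <- t(A) %*% X + X %*% A + C
    rel <- norm(res, "F") / max(norm(C, "F"), 1e-300)
    if (!is.finite(rel) || rel > tol) {
      stop(sprintf("lyap_solve: relative residual %.3g exceeds tol %.3g",
                   rel, tol))
    }
  }
  X
}

## Shifted variant: solves (A - s I)^T X + X (A - s I) + C = 0 reusing the
## factorization of A (only the eigenvalues shift).
lyap_solve_shifted <- function(fac, s, C) {
  lam <- fac$values - s
  den <- outer(lam, lam, `+`)
  Ct <- t(fac$V) %*% C %*% fac$V
  Xt <- -Ct / den
  X <- Re(t(fac$Vi) %*% Xt %*% fac$Vi)
  (X + t(X)) / 2
}

#' Solve the continuous-time algebraic Riccati equation
#'
#' Solves \eqn{A^T P + P A - P B B^T P / \lambda + Q = 0}. For Hurwitz-stable
#' \code{A} the Newton-Kleinman iteration is used (each step a Schur-based
#' Lyapunov solve, robust to defective matrices); otherwise the stable
#' invariant subspace of the Hamiltonian matrix
#' \eqn{H = [A, -BB^T/\lambda; -Q, -A^T]} is computed.
#'
#' @param A state matrix (n x n).
#' @param Q symmetric positive semidefinite state weighting (n x n).
#' @param lambda positive input-energy penalty.
#' @param B input matrix (n x m); identity by default.
#' @param tol relative residual tolerance for the defining equation.
#' @return symmetric positive semidefinite \code{P}.
#' @export
care_solve <- function(A, Q, lambda, B = NULL, tol = 1e-7) {
  n <- nrow(A)
  BBt <- if (is.null(B)) diag(n) else B %*% t(B)
  resid <- function(P) {
    res <- t(A) %*% P + P %*% A - P %*% BBt %*% P / lambda + Q
    norm(res, "F") / max(norm(Q, "F"), 1e-300)
  }
  if (spectral_abscissa(A) < 0) {
    ## Newton-Kleinman from the stabilizing start P = 0:
    ## (A - G P_i)' P_{i+1} + P_{i+1} (A - G P_i) + Q + P_i G P_i = 0
    G <- BBt / lambda
    P <- matrix(0, n, n)
    for (it in 1:60) {
      Acl <- A - G %*% P
      Qi <- Q + P %*% G %*% P
      Pn <- lyap_pair_cpp(Acl, Qi, diag(n), FALSE)$P
      done <- norm(Pn - P, "F") <= 1e-13 * max(norm(Pn, "F"), 1)
      P <- Pn
      if (done || resid(P) < tol) break
    }
    if (resid(P) <= max(tol, 1e-9)) return((P + t(P)) / 2)
    ## fall through to the Hamiltonian route on non-convergence
  }
  H <- rbind(cbind(A, -BBt / lambda),
             cbind(-Q, -t(A)))
  e <- eigen(H)
  idx <- order(Re(e$values))[seq_len(n)]
  if (max(Re(e$values[idx])) >= -1e-12) {
    stop("care_solve: Hamiltonian has fewer than n strictly stable ",
         "eigenvalues; pair may not be stabilizable/detectable")
  }
  U <- e$vectors[, idx, drop = FALSE]
  U1 <- U[seq_len(n), , drop = FALSE]
  U2 <- U[n + seq_len(n), , drop = FALSE]
  P <- Re(U2 %*% solve(U1))
  P <- (P + t(P)) / 2
  rel <- resid(P)
  if (!is.finite(rel) || rel > max(tol, 1e-9)) {
    stop(sprintf("care_solve: Riccati residual %.3g exceeds tol %.3g",
                 rel, tol))
  }
  P
}

#' Matrix exponential (eigendecomposition route)
#'
#' Dense matrix exponential used for closed-form linear-regime checks; assumes
#' a diagonalizable argument, which holds generically for the random
#' connectivities used here.
#'
#' @param M square matrix.
#' @return \code{expm(M)}.
#' @export
expm_eig <- function(M) {
  e <- eigen(M)
  Re(e$vectors %*% (exp(e$values) * solve(e$vectors)))
}

## Orthonormal basis of the column space of M (columns), via QR with a
## rank tolerance.
orth_basis <- function(M, tol = 1e-10) {
  qr_ <- qr(M)
  r <- sum(abs(diag(qr_$qr)) > tol * max(abs(diag(qr_$qr)), 1))
  qr.Q(qr_)[, seq_len(max(r, 1)), drop = FALSE]
}

## Principal angles (degrees) between the column spaces of two orthonormal
## bases, via singular values of U^T V.
principal_angles <- function(U, V) {
  s <- svd(crossprod(U, V))$d
  s <- pmin(pmax(s, -1), 1)
  acos(s) * 180 / pi
}
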
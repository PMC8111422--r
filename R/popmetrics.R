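## Population-geometry metrics: dimensionality, nonnormality, subspace
## potency and alignment, rotational dynamics, canonical correlations.

#' Participation ratio
#'
#' Effective dimensionality \eqn{(\sum_i \sigma_i)^2 / \sum_i \sigma_i^2} of
#' a non-negative spectrum.
#'
#' @param sigma eigenvalues of a symmetric PSD matrix (small negative values
#'   from roundoff are clipped to zero).
#' @return scalar in [1, length(sigma)].
#' @export
participation_ratio <- function(sigma) {
  sigma <- pmax(sigma, 0)
  s <- sum(sigma)
  if (s <= 0) stop("participation_ratio: all-zero spectrum")
  s^2 / sum(sigma^2)
}

#' Nonnormality index
#'
#' \eqn{(\|W\|_F^2 - \|\Lambda\|_F^2) / \|W\|_F^2}, where \eqn{\Lambda} holds
#' the eigenvalues of \code{W}; equals the fraction of Frobenius energy in
#' the strictly upper-triangular part of the Schur form (0 for normal
#' matrices, 1 for nilpotent ones).
#'
#' @param W square matrix.
#' @return scalar in [0, 1].
#' @export
nonnormality_index <- function(W) {
  f2 <- sum(W^2)
  if (f2 == 0) stop("nonnormality_index: zero matrix")
  ev <- eigen(W, only.values = TRUE)$values
  max((f2 - sum(Mod(ev)^2)) / f2, 0)
}

#' H2 norm of a stable network
#'
#' \eqn{Tr(W_o)} where the full-state observability Gramian solves
#' \eqn{A^T W_o + W_o A + I = 0} (with \eqn{A = W - I}); the total impulse
#' response energy summed over units.
#'
#' @param A Hurwitz-stable state matrix.
#' @return positive scalar.
#' @export
h2_norm <- function(A) {
  if (spectral_abscissa(A) >= 0) stop("h2_norm: A is not Hurwitz-stable")
  sum(diag(lyap_solve(A, diag(nrow(A)))))
}

#' Prospective motor potency of a subspace
#'
#' Mean Rayleigh quotient \eqn{\frac{1}{K}\sum_i d_i^T Q d_i} over an
#' orthonormal basis.
#'
#' @param Q Gramian.
#' @param basis N x K matrix with orthonormal columns.
#' @return scalar potency.
#' @export
subspace_potency <- function(Q, basis) {
  if (!is.matrix(basis)) basis <- matrix(basis, ncol = 1)
  G <- crossprod(basis)
  if (max(abs(G - diag(ncol(basis)))) > 1e-8) {
    stop("subspace_potency: basis columns are not orthonormal")
  }
  mean(colSums(basis * (Q %*% basis)))
}

#' Amplification factor time course
#'
#' \eqn{\|x(t) - x_{sp}\| / \|x^* - x_{sp}\|} along an autonomous
#' movement-epoch trajectory started at \eqn{x^*} (no external inputs).
#'
#' @param traj a \code{prepctrl_trajectory} (conditions in the third slot).
#' @param x_star N x k matrix of initial states (must equal
#'   \code{traj$x[ , 1, ]}).
#' @param x_sp spontaneous state.
#' @return nt x k matrix of amplification factors (first row = 1).
#' @export
amplification_factor <- function(traj, x_star, x_sp) {
  if (!is.matrix(x_star)) x_star <- matrix(x_star, ncol = 1)
  denom <- sqrt(colSums((x_star - x_sp)^2))
  if (any(denom < 1e-12)) stop("amplification_factor: x_star equals x_sp")
  nt <- dim(traj$x)[2]
  out <- matrix(NA_real_, nt, ncol(x_star))
  for (i in seq_len(nt)) {
    d <- matrix(traj$x[, i, ], ncol = ncol(x_star)) - x_sp
    out[i, ] <- sqrt(colSums(d^2)) / denom
  }
  out
}

## Flatten a rate tensor (neurons x time x conditions) to neurons x samples
## and remove each neuron's mean across time and conditions.
center_tensor <- function(data) {
  M <- matrix(data, nrow = dim(data)[1])
  M - rowMeans(M)
}

#' Epoch container for rate tensors
#'
#' @param rates neurons x time x conditions array of firing rates.
#' @param epoch label, e.g. \code{"prep"} or \code{"move"}.
#' @param window_ms optional 2-vector documenting the window.
#' @return object of class \code{prepctrl_epoch}.
#' @export
epoch_data <- function(rates, epoch = "prep", window_ms = NULL) {
  stopifnot(length(dim(rates)) == 3)
  structure(list(rates = rates, epoch = epoch, window_ms = window_ms),
            class = "prepctrl_epoch")
}

## Covariance (neurons x neurons) of a mean-centered epoch.
epoch_cov <- function(ep) {
  M <- center_tensor(ep$rates)
  tcrossprod(M) / (ncol(M) - 1)
}

#' Participation ratio of epoch activity
#'
#' @param ep a \code{prepctrl_epoch}.
#' @return participation ratio of the eigenvalues of the across-time-and-
#'   condition activity covariance.
#' @export
epoch_dimensionality <- function(ep) {
  ev <- eigen(epoch_cov(ep), symmetric = TRUE, only.values = TRUE)$values
  participation_ratio(ev)
}

#' Alignment index between preparatory and movement activity
#'
#' Fraction of preparatory-epoch variance captured by the top-K principal
#' components of movement-epoch activity, normalized by the variance captured
#' by the top-K preparatory PCs:
#' \eqn{Tr(D_{move}^T C_{prep} D_{move}) / \sum_{i=1}^K \sigma^2_{i,prep}},
#' with K the smallest number of prep-PCs capturing \code{var_threshold} of
#' preparatory variance. All covariances are computed after removing each
#' neuron's mean across time and conditions.
#'
#' @param prep,move \code{prepctrl_epoch} objects.
#' @param var_threshold variance fraction defining K (0.8).
#' @return scalar in [0, 1].
#' @export
alignment_index <- function(prep, move, var_threshold = 0.8) {
  Cp <- epoch_cov(prep)
  Cm <- epoch_cov(move)
  ep <- eigen(Cp, symmetric = TRUE)
  if (max(ep$values) <= 0) stop("alignment_index: degenerate prep covariance")
  cum <- cumsum(ep$values) / sum(pmax(ep$values, 0))
  K <- which(cum >= var_threshold)[1]
  em <- eigen(Cm, symmetric = TRUE)
  D <- em$vectors[, seq_len(K), drop = FALSE]
  sum(colSums(D * (Cp %*% D))) / sum(ep$values[seq_len(K)])
}

#' Fit rotational (jPCA-style) dynamics
#'
#' Reduces the rate tensor to \code{n_pc} principal components, estimates
#' state derivatives by finite differences, and fits the best skew-symmetric
#' generator \eqn{\dot x = S x} by least squares (closed form: \eqn{S\Sigma +
#' \Sigma S = A_1 - A_1^T} with \eqn{\Sigma = XX^T}, \eqn{A_1 = \dot X X^T},
#' solved in the eigenbasis of \eqn{\Sigma}; the solution is exactly
#' skew-symmetric). Returns the projection onto the plane of the top
#' rotation.
#'
#' @param data neurons x time x conditions rate tensor.
#' @param dt time step of the tensor, ms.
#' @param n_pc PCA dimensionality before fitting (6).
#' @return list: \code{S} (skew generator in PC space), \code{basis}
#'   (neurons x n_pc), \code{plane} (neurons x 2 jPC plane),
#'   \code{projections} (2 x time x conditions), \code{r2} of the skew fit.
#' @export
jpca <- function(data, dt = 1, n_pc = 6) {
  N <- dim(data)[1]; nt <- dim(data)[2]; k <- dim(data)[3]
  if (nt < 3) stop("jpca: insufficient samples")
  M <- center_tensor(data)
  pc <- svd(M, nu = min(n_pc, N))
  B <- pc$u[, seq_len(min(n_pc, N)), drop = FALSE]
  Xr <- array(crossprod(B, M), c(ncol(B), nt, k))
  ## finite-difference derivatives (per condition, central)
  Xs <- NULL; dXs <- NULL
  for (j in seq_len(k)) {
    x <- Xr[, , j]
    dx <- (x[, 3:nt, drop = FALSE] - x[, 1:(nt - 2), drop = FALSE]) / (2 * dt)
    Xs <- cbind(Xs, x[, 2:(nt - 1), drop = FALSE])
    dXs <- cbind(dXs, dx)
  }
  Sig <- tcrossprod(Xs)
  A1 <- tcrossprod(dXs, Xs)
  Csk <- A1 - t(A1)
  es <- eigen(Sig, symmetric = TRUE)
  Ct <- crossprod(es$vectors, Csk %*% es$vectors)
  den <- outer(es$values, es$values, `+`)
  den[den < 1e-12 * max(den, 1e-300)] <- Inf   # degenerate directions
  S <- es$vectors %*% (Ct / den) %*% t(es$vectors)
  S <- (S - t(S)) / 2                      # exact skew symmetry
  r2 <- 1 - sum((dXs - S %*% Xs)^2) / sum(dXs^2)
  ev <- eigen(S)
  top <- order(-abs(Im(ev$values)))[1]
  v <- ev$vectors[, top]
  plane_pc <- qr.Q(qr(cbind(Re(v), Im(v))))
  proj <- array(NA_real_, c(2, nt, k))
  for (j in seq_len(k)) proj[, , j] <- crossprod(plane_pc, Xr[, , j])
  list(S = S, basis = B, plane = B %*% plane_pc, projections = proj, r2 = r2)
}

#' Canonical correlations between two data sets
#'
#' Reduces each rate tensor by PCA to the smallest dimensionality capturing
#' \code{var_kept} of its variance, then computes canonical correlations
#' between the reduced time series.
#'
#' @param dataA,dataB neurons x time x conditions tensors with matching
#'   time/condition layout (neuron counts may differ).
#' @param var_kept variance fraction kept in the PCA reduction (0.95).
#' @return non-increasing vector of canonical correlations in [0, 1].
#' @export
cca_compare <- function(dataA, dataB, var_kept = 0.95) {
  reduce <- function(d) {
    M <- center_tensor(d)
    s <- svd(M)
    cum <- cumsum(s$d^2) / sum(s$d^2)
    K <- which(cum >= var_kept)[1]
    crossprod(s$u[, seq_len(K), drop = FALSE], M)
  }
  X <- t(reduce(dataA)); Y <- t(reduce(dataB))
  if (nrow(X) != nrow(Y)) stop("cca_compare: sample counts differ")
  if (nrow(X) <= max(ncol(X), ncol(Y))) stop("cca_compare: too few samples")
  cc <- stats::cancor(X, Y)
  sort(pmin(pmax(cc$cor, 0), 1), decreasing = TRUE)
}
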
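## Prospective motor error, observability Gramian, and linear-quadratic
## preparatory control (designed on the linearized dynamics, executed on the
## nonlinear circuit).

#' Observability Gramian of the motor readout
#'
#' Solves the Lyapunov equation \eqn{A^T Q + Q A + C^T C = 0} for the
#' observability Gramian of the pair \eqn{(A, C)}, then rescales so that
#' \eqn{Tr(Q) = N}. The quadratic form \eqn{(x - x^*)^T Q (x - x^*)} is the
#' prospective motor error: the integrated squared torque error that would
#' result if the uncontrolled movement-epoch dynamics were released from
#' \eqn{x} instead of \eqn{x^*}.
#'
#' For unstable \code{A} (chaotic networks) the integral diverges; following
#' the model's convention, \code{Q = I} is returned when
#' \code{allow_unstable = TRUE}.
#'
#' @param A effective state matrix (\eqn{W - I}).
#' @param C readout matrix (2 x N).
#' @param normalize rescale so that \code{Tr(Q) = N} (skipped when the
#'   unnormalized trace is zero).
#' @param allow_unstable return the identity Gramian for unstable \code{A}
#'   instead of erroring.
#' @return symmetric positive semidefinite \code{Q}.
#' @export
observability_gramian <- function(A, C, normalize = TRUE,
                                  allow_unstable = FALSE) {
  N <- nrow(A)
  if (spectral_abscissa(A) >= 0) {
    if (allow_unstable) return(diag(N))
    stop("observability_gramian: A is not Hurwitz-stable; for chaotic ",
         "networks use allow_unstable = TRUE (Q = I)")
  }
  Q <- lyap_solve(A, crossprod(C))
  trQ <- sum(diag(Q))
  if (normalize && trQ > 0) Q <- Q * (N / trQ)
  Q
}

#' Prospective motor error
#'
#' @param x state vector (or N x k matrix).
#' @param x_star reference preparatory state (vector or matching matrix).
#' @param Q Gramian from \code{\link{observability_gramian}}.
#' @return non-negative scalar (or length-k vector): \eqn{(x - x^*)^T Q
#'   (x - x^*)}.
#' @export
prospective_error <- function(x, x_star, Q) {
  d <- x - x_star
  if (!is.matrix(d)) d <- matrix(d, ncol = 1)
  drop(colSums(d * (Q %*% d)))
}

#' Optimal preparatory feedback gain (LQR)
#'
#' Solves the Riccati equation \eqn{A^T P + P A - P P / \lambda + Q = 0} and
#' returns the linear state-feedback law \eqn{\delta u = K \delta x} with
#' \eqn{K = -P/\lambda}. The gain is condition-independent; only the steady
#' input \eqn{u^*} depends on the movement.
#'
#' @param A effective state matrix.
#' @param Q state weighting (normalized observability Gramian).
#' @param lambda input energy penalty (0.1 for the cortical model).
#' @return object of class \code{prepctrl_law}: \code{Q}, \code{P}, \code{K},
#'   \code{lambda}, closed-loop matrix \code{A_cl = A + K}.
#' @export
lqr_gain <- function(A, Q, lambda = 0.1) {
  P <- care_solve(A, Q, lambda)
  K <- -P / lambda
  A_cl <- A + K
  if (spectral_abscissa(A_cl) >= 0) {
    stop("lqr_gain: closed loop not stable (unexpected)")
  }
  structure(list(Q = Q, P = P, K = K, lambda = lambda, A_cl = A_cl),
            class = "prepctrl_law")
}

#' @export
print.prepctrl_law <- function(x, ...) {
  cat(sprintf("<prepctrl_law: N=%d, lambda=%g, |K|_F=%.3g, abscissa(A+K)=%.3f>\n",
              nrow(x$K), x$lambda, norm(x$K, "F"), spectral_abscissa(x$A_cl)))
  invisible(x)
}

#' Movement-specific steady control input
#'
#' \eqn{u^* = x^* - W\phi(x^*) - \bar h}, which establishes \eqn{x^*} as a
#' fixed point of the nonlinear dynamics under constant input (the "naive
#' feedforward" preparatory strategy uses exactly this input with no
#' feedback).
#'
#' @param x_star target preparatory state (vector or N x k matrix).
#' @param model a \code{prepctrl_network}.
#' @return vector or matrix of steady inputs.
#' @export
steady_input <- function(x_star, model) {
  x_star - model$W %*% relu(x_star) - model$h_bar
}

#' Simulate optimally controlled preparation followed by movement
#'
#' During preparation the nonlinear circuit receives \eqn{u(t) = u^* +
#' K(x - x^*)} (or the naive feedforward input \eqn{u^*} alone when
#' \code{law} is \code{NULL}); torques are clamped to zero. At switch-off the
#' circuit runs autonomously (plus the condition-independent bump for
#' ISN-class tasks), drives the arm, and hand trajectories are produced.
#'
#' @param task a calibrated \code{prepctrl_task}.
#' @param law a \code{prepctrl_law} from \code{\link{lqr_gain}}, or
#'   \code{NULL} for naive feedforward preparation.
#' @param prep_ms preparation duration, ms.
#' @param move_ms movement-epoch duration, ms.
#' @param x0 initial state at preparation onset (default: spontaneous).
#' @param dt Euler step, ms.
#' @return list: \code{prep} and \code{move} trajectories, torques \code{m}
#'   (movement epoch), hand paths, \code{endpoint_err_m} (max over
#'   conditions), and per-condition prospective error time courses during
#'   preparation (\code{prosp}).
#' @export
prepare_lqr <- function(task, law, prep_ms, move_ms = 800, x0 = NULL, dt = 1) {
  model <- task$model
  N <- model$N; k <- ncol(task$x_star)
  if (is.null(x0)) x0 <- matrix(model$x_sp, N, k)
  u_star <- steady_input(task$x_star, model)
  Kmat <- if (is.null(law)) NULL else law$K
  u_fn <- function(t, X) {
    du <- if (is.null(Kmat)) 0 else Kmat %*% (X - task$x_star)
    u_star + du
  }
  prep <- simulate(model, prep_ms, x0 = x0, u_fn = u_fn, dt = dt,
                   linear = isTRUE(task$linear))
  nt_p <- length(prep$times)
  x_end <- matrix(prep$x[, nt_p, ], N, k)
  h_fn <- if (task$include_h) function(t) transient_input(t, t_move = 0) else NULL
  move <- simulate(model, move_ms, x0 = x_end, h_fn = h_fn, dt = dt,
                   linear = isTRUE(task$linear))
  nt_m <- length(move$times)
  m <- array(NA_real_, c(2, nt_m, k))
  for (j in seq_len(k)) m[, , j] <- task$C %*% move$rates[, , j]
  arm <- arm_simulate(m, dt, task$targets$params)
  ## compare against target hand paths on the overlapping horizon
  idx <- seq_len(min(nt_m, dim(task$targets$hand)[2]))
  endpoint <- sqrt(colSums((arm$hand[, max(idx), ] -
                              task$targets$hand[, max(idx), ])^2))
  Q <- if (!is.null(law)) law$Q else NULL
  prosp <- NULL
  if (!is.null(Q)) {
    prosp <- matrix(NA_real_, nt_p, k)
    for (i in seq_len(nt_p)) {
      prosp[i, ] <- prospective_error(matrix(prep$x[, i, ], N, k),
                                      task$x_star, Q)
    }
  }
  list(prep = prep, move = move, m = m, hand = arm$hand,
       endpoint_err_m = max(endpoint), endpoint_err = endpoint,
       prosp = prosp, prep_ms = prep_ms)
}

#' Control cost decomposition
#'
#' For the closed-loop law \eqn{K = -P/\lambda}, the total cost from initial
#' deviation \eqn{\delta x_0} is \eqn{J = \delta x_0^T P \delta x_0}; the
#' energy part is \eqn{\delta x_0^T Y \delta x_0} with
#' \eqn{A_{cl}^T Y + Y A_{cl} + P P / \lambda^2 = 0}, and the integrated
#' prospective cost is \eqn{\delta x_0^T (P - \lambda Y) \delta x_0}.
#'
#' @param law a \code{prepctrl_law}.
#' @param dx0 initial deviation vector (or N x k matrix).
#' @return list of class \code{prepctrl_cost}: \code{total}, \code{energy},
#'   \code{prospective} (vectors over conditions), and the energy Gramian
#'   \code{Y}.
#' @export
cost_report <- function(law, dx0) {
  Y <- lyap_solve(law$A_cl, law$P %*% law$P / law$lambda^2)
  d <- if (is.matrix(dx0)) dx0 else matrix(dx0, ncol = 1)
  total <- drop(colSums(d * (law$P %*% d)))
  energy <- drop(colSums(d * (Y %*% d)))
  structure(list(total = total, energy = energy,
                 prospective = total - law$lambda * energy, Y = Y),
            class = "prepctrl_cost")
}

#' Nullspace-weighted Gramian
#'
#' Blends the prospective-error Gramian with an immediate-output penalty:
#' \eqn{\tilde Q = \eta Q + (1 - \eta) N C^T C / Tr(C^T C)}. Preparing under
#' \eqn{\tilde Q} additionally suppresses output torques during preparation.
#'
#' @param Q normalized observability Gramian.
#' @param C readout matrix.
#' @param eta weight in [0, 1] on the prospective term (default 0.2).
#' @return blended Gramian with \eqn{Tr = N}.
#' @export
nullspace_weighted_gramian <- function(Q, C, eta = 0.2) {
  stopifnot(eta >= 0, eta <= 1)
  N <- nrow(Q)
  CtC <- crossprod(C)
  eta * Q + (1 - eta) * N * CtC / sum(diag(CtC))
}
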
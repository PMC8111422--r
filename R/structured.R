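## Biologically constrained preparatory feedback: structured (output)
## feedback gains, Dale-law factorization, lagged thalamo-cortical loop and
## basal-ganglia gating.

#' Define a structured static-gain synthesis problem
#'
#' The controller is \eqn{u = Z \Gamma x} with free matrix \code{Z}; the
#' selector \eqn{\Gamma} restricts which state components feedback may read
#' (e.g. excitatory cells only, or the thalamic block of an augmented
#' system). The cost is \eqn{J(Z) = Tr(P)} with
#' \eqn{A_{cl}^T P + P A_{cl} + Q + \lambda \Gamma^T Z^T B^T B Z \Gamma = 0}
#' and \eqn{A_{cl} = A + B Z \Gamma}.
#'
#' @param A state matrix.
#' @param B input matrix (identity if \code{NULL}).
#' @param Q state weighting.
#' @param Gamma selector matrix (rows = read-out components).
#' @param lambda input energy penalty.
#' @return list of class \code{prepctrl_sgp}.
#' @export
structured_gain_problem <- function(A, Q, Gamma, lambda, B = NULL) {
  n <- nrow(A)
  if (is.null(B)) B <- diag(n)
  structure(list(A = A, B = B, Q = Q, Gamma = Gamma, lambda = lambda),
            class = "prepctrl_sgp")
}

## Cost and analytic gradient of Tr(P) w.r.t. Z, via the two Lyapunov
## equations of the Lagrangian stationarity conditions. Returns Inf cost for
## destabilizing Z.
sgp_cost_grad <- function(prob, Z, with_grad = TRUE) {
  A <- prob$A; B <- prob$B; Gam <- prob$Gamma; lam <- prob$lambda
  n <- nrow(A)
  K <- Z %*% Gam
  Acl <- A + B %*% K
  if (spectral_abscissa(Acl) >= -1e-9) {
    return(list(J = Inf, grad = NULL))
  }
  BK <- B %*% K
  Qhat <- prob$Q + lam * crossprod(BK)
  ## Schur-based solves: augmented loop systems are defective (repeated lag
  ## eigenvalues), so eigendecomposition solvers are not applicable here
  sol <- lyap_pair_cpp(Acl, Qhat, diag(n), with_grad)
  P <- sol$P
  J <- sum(diag(P))
  if (!with_grad) return(list(J = J, P = P))
  S <- sol$S
  grad <- 2 * t(B) %*% (P + lam * BK) %*% S %*% t(Gam)
  list(J = J, grad = grad, P = P, S = S)
}

#' Optimize a structured feedback gain
#'
#' Minimizes \eqn{Tr(P)} over the free matrix \code{Z} by L-BFGS with the
#' analytic Lagrangian gradient \eqn{2 B^T (P + \lambda B Z \Gamma) S
#' \Gamma^T}. By default the optimization starts from the least-squares
#' restriction of the unconstrained LQR gain,
#' \eqn{Z_0 = \bar K \Gamma^T (\Gamma \Gamma^T)^{-1}} (halved until the loop
#' is stable if necessary).
#'
#' @param prob a \code{\link{structured_gain_problem}}.
#' @param Z0 optional initial \code{Z}.
#' @param maxit L-BFGS iteration cap.
#' @param factr L-BFGS convergence factor.
#' @return list: optimal \code{Z}, gain \code{K = Z Gamma}, cost \code{J},
#'   initial cost \code{J0}, unconstrained LQR cost \code{J_lqr}, and the
#'   unconstrained gain \code{K_lqr}.
#' @export
optimize_structured_gain <- function(prob, Z0 = NULL, maxit = 150,
                                     factr = 1e7) {
  A <- prob$A; B <- prob$B; Gam <- prob$Gamma; lam <- prob$lambda
  Pbar <- care_solve(A, prob$Q, lam, B = B)
  K_lqr <- -t(B) %*% Pbar / lam
  J_lqr <- sum(diag(Pbar))
  if (is.null(Z0)) {
    Z0 <- K_lqr %*% t(Gam) %*% solve(tcrossprod(Gam))
    for (i in 1:30) {
      if (is.finite(sgp_cost_grad(prob, Z0, with_grad = FALSE)$J)) break
      Z0 <- Z0 / 2
      if (i == 30) stop("optimize_structured_gain: no stable initialization")
    }
  }
  dims <- dim(Z0)
  big <- 1e12
  fn <- function(p) {
    out <- sgp_cost_grad(prob, matrix(p, dims[1], dims[2]), with_grad = FALSE)
    if (!is.finite(out$J)) big else out$J
  }
  gr <- function(p) {
    out <- sgp_cost_grad(prob, matrix(p, dims[1], dims[2]))
    if (!is.finite(out$J)) return(rep(0, length(p)))
    as.numeric(out$grad)
  }
  J0 <- sgp_cost_grad(prob, Z0, with_grad = FALSE)$J
  opt <- stats::optim(as.numeric(Z0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = factr))
  Z <- matrix(opt$par, dims[1], dims[2])
  J <- sgp_cost_grad(prob, Z, with_grad = FALSE)$J
  if (J > J0 + 1e-9) { Z <- Z0; J <- J0 }   # never return worse than init
  list(Z = Z, K = Z %*% Gam, J = J, J0 = J0, J_lqr = J_lqr, K_lqr = K_lqr,
       convergence = opt$convergence)
}

#' Sign-constrained factorization of a feedback matrix
#'
#' Decomposes \eqn{Z \approx K_{xz} K_{zy}} where \code{Kzy} (thalamus to
#' cortical layer 4) is elementwise non-negative and \code{Kxz} (layer 4 to
#' the recurrent network) has \code{m_exc} non-negative and \code{m_inh}
#' non-positive columns. Each entry is parameterized as \eqn{\pm z^2} and the
#' normalized squared reconstruction error plus an L2 penalty
#' \eqn{\gamma(\|K_{xz}\|_F^2 + \|K_{zy}\|_F^2)} is minimized by L-BFGS.
#'
#' @param Z matrix to factorize (N x NE).
#' @param m_exc,m_inh numbers of excitatory / inhibitory layer-4 units
#'   (100, 100).
#' @param gamma L2 penalty weight (1e-4).
#' @param seed RNG seed for the initialization.
#' @param maxit L-BFGS iteration cap.
#' @param tol relative reconstruction error above which a warning suggests a
#'   larger layer-4 population.
#' @return list: \code{Kxz} (N x M), \code{Kzy} (M x NE), relative error
#'   \code{rel_err}, \code{sign_cols} of \code{Kxz}.
#' @export
dale_decompose <- function(Z, m_exc = 100, m_inh = 100, gamma = 1e-4,
                           seed = 0, maxit = 500, tol = 0.05) {
  N <- nrow(Z); NE <- ncol(Z); M <- m_exc + m_inh
  sgn <- rep(c(1, -1), c(m_exc, m_inh))
  z2 <- sum(Z^2)
  set.seed(seed)
  sc <- (sqrt(z2 / (N * NE)) / sqrt(M))^0.5
  P0 <- matrix(abs(stats::rnorm(N * M, 0, sc)), N, M)
  Q0 <- matrix(abs(stats::rnorm(M * NE, 0, sc)), M, NE)
  unpack <- function(p) list(P = matrix(p[seq_len(N * M)], N, M),
                             Qm = matrix(p[-seq_len(N * M)], M, NE))
  fn <- function(p) {
    q <- unpack(p)
    Kxz <- sweep(q$P^2, 2, sgn, `*`); Kzy <- q$Qm^2
    sum((Z - Kxz %*% Kzy)^2) / z2 + gamma * (sum(Kxz^2) + sum(Kzy^2))
  }
  gr <- function(p) {
    q <- unpack(p)
    Kxz <- sweep(q$P^2, 2, sgn, `*`); Kzy <- q$Qm^2
    Rres <- (Kxz %*% Kzy - Z) * (2 / z2)
    gKxz <- Rres %*% t(Kzy) + 2 * gamma * Kxz
    gKzy <- crossprod(Kxz, Rres) + 2 * gamma * Kzy
    gP <- gKxz * sweep(2 * q$P, 2, sgn, `*`)
    gQ <- gKzy * (2 * q$Qm)
    c(as.numeric(gP), as.numeric(gQ))
  }
  opt <- stats::optim(c(as.numeric(P0), as.numeric(Q0)), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e5))
  q <- unpack(opt$par)
  Kxz <- sweep(q$P^2, 2, sgn, `*`); Kzy <- q$Qm^2
  rel <- norm(Z - Kxz %*% Kzy, "F") / sqrt(z2)
  if (rel > tol) {
    warning(sprintf(paste0("dale_decompose: relative error %.3f exceeds %.3f;",
                           " consider a larger layer-4 population"), rel, tol))
  }
  list(Kxz = Kxz, Kzy = Kzy, rel_err = rel, sign_cols = sgn)
}

#' Augmented state-space for the lagged thalamo-cortical loop
#'
#' Builds the design system in which thalamus (\code{y}, time constant
#' \code{tau_y}) integrates a sparse random projection \code{R} of cortical
#' activity, layer 4 (\code{z}, \code{tau_z}) integrates \code{y} with unit
#' weights, and control enters cortex reading only the \code{z} block:
#' state \eqn{(x, y, z)}, \eqn{\Gamma = [0\ 0\ I]}, \eqn{B' = [I; 0; 0]},
#' \eqn{Q'} zero-padded.
#'
#' @param model a \code{prepctrl_network} (provides \eqn{A = W - I} and
#'   \eqn{\tau}).
#' @param Q prospective-error Gramian for the cortical block.
#' @param lambda input energy penalty (0.01 for the loop).
#' @param p density of the random cortex-to-thalamus projection (0.2).
#' @param tau_y,tau_z thalamic / layer-4 time constants, ms (10, 10).
#' @param seed RNG seed for \code{R}.
#' @return a \code{\link{structured_gain_problem}} with extra fields
#'   \code{R}, \code{n}, \code{n_exc}, \code{tau_y}, \code{tau_z}.
#' @export
build_augmented_system <- function(model, Q, lambda = 0.01, p = 0.2,
                                   tau_y = 10, tau_z = 10, seed = 0) {
  N <- model$N; NE <- model$n_exc; tau <- model$tau
  A <- model$W - diag(N)
  set.seed(seed)
  R <- matrix((stats::runif(NE * NE) < p) * 1, NE, NE)
  if (abs(det(R)) < 1e-12) {
    warning("build_augmented_system: R is numerically singular; ",
            "loss equivalence with direct E-only feedback may not hold")
  }
  Z0 <- matrix(0, N, NE)
  A_aug <- rbind(
    cbind(A, matrix(0, N, NE), matrix(0, N, NE)),
    cbind((tau / tau_y) * cbind(R, matrix(0, NE, N - NE)),
          -(tau / tau_y) * diag(NE), matrix(0, NE, NE)),
    cbind(matrix(0, NE, N), (tau / tau_z) * diag(NE),
          -(tau / tau_z) * diag(NE)))
  B_aug <- rbind(diag(N), matrix(0, 2 * NE, N))
  Q_aug <- rbind(cbind(Q, matrix(0, N, 2 * NE)),
                 matrix(0, 2 * NE, N + 2 * NE))
  Gamma <- cbind(matrix(0, NE, N + NE), diag(NE))
  prob <- structured_gain_problem(A_aug, Q_aug, Gamma, lambda, B = B_aug)
  prob$R <- R; prob$n <- N; prob$n_exc <- NE
  prob$tau_y <- tau_y; prob$tau_z <- tau_z
  prob
}

#' Build the gated thalamo-cortical control circuit
#'
#' Full synthesis pipeline: observability Gramian of the calibrated readout,
#' structured-gain optimization on the lagged augmented system, sign-
#' constrained factorization \eqn{Z = K_{xz} K_{zy}}, rebalancing of the
#' three loop matrices to equal Frobenius norms (leaving the loop gain
#' unchanged), and per-condition steady inputs
#' \eqn{\tilde u^* = x^* - (W + K)\phi(x^*) - \bar h} with
#' \eqn{K = K_{xz} K_{zy} K_{yx}}.
#'
#' @param task a calibrated \code{prepctrl_task}.
#' @param lambda input energy penalty (0.01).
#' @param m_exc,m_inh layer-4 population sizes (100, 100).
#' @param p cortex-to-thalamus connection density (0.2).
#' @param tau_y,tau_z loop time constants, ms.
#' @param seed RNG seed (projection \code{R} and factorization init).
#' @param maxit_gain,maxit_dale iteration caps.
#' @return object of class \code{prepctrl_loop}: connection matrices
#'   \code{Kyx}, \code{Kzy}, \code{Kxz}, effective gain \code{K}, steady
#'   inputs \code{u_star} (N x 8), time constants, the underlying task, and
#'   synthesis diagnostics.
#' @export
build_loop_circuit <- function(task, lambda = 0.01, m_exc = 100, m_inh = 100,
                               p = 0.2, tau_y = 10, tau_z = 10, seed = 0,
                               maxit_gain = 150, maxit_dale = 500) {
  model <- task$model
  N <- model$N; NE <- model$n_exc
  A <- model$W - diag(N)
  Q <- observability_gramian(A, task$C, allow_unstable = TRUE)
  prob <- build_augmented_system(model, Q, lambda = lambda, p = p,
                                 tau_y = tau_y, tau_z = tau_z, seed = seed)
  gain <- optimize_structured_gain(prob, maxit = maxit_gain)
  fact <- dale_decompose(gain$Z, m_exc = m_exc, m_inh = m_inh, seed = seed,
                         maxit = maxit_dale)
  Kyx <- cbind(prob$R, matrix(0, NE, N - NE))
  ## rebalance to equal Frobenius norms; the triple product is unchanged
  n1 <- norm(fact$Kxz, "F"); n2 <- norm(fact$Kzy, "F"); n3 <- norm(Kyx, "F")
  g <- (n1 * n2 * n3)^(1 / 3)
  Kxz <- fact$Kxz * (g / n1); Kzy <- fact$Kzy * (g / n2)
  Kyx <- Kyx * (g / n3)
  K <- Kxz %*% Kzy %*% Kyx
  u_star <- task$x_star - (model$W + K) %*% relu(task$x_star) - model$h_bar
  structure(list(Kyx = Kyx, Kzy = Kzy, Kxz = Kxz, K = K, R = prob$R,
                 u_star = u_star, tau_y = tau_y, tau_z = tau_z,
                 lambda = lambda, task = task, Q = Q,
                 synthesis = list(J = gain$J, J0 = gain$J0,
                                  J_lqr = gain$J_lqr,
                                  dale_rel_err = fact$rel_err),
                 Z = gain$Z),
            class = "prepctrl_loop")
}

#' @export
print.prepctrl_loop <- function(x, ...) {
  cat(sprintf(paste0("<prepctrl_loop: N=%d thal=%d L4=%d, lambda=%g, ",
                     "Tr(P) loop/LQR = %.2f, Dale rel err %.3f>\n"),
              nrow(x$K), nrow(x$Kyx), ncol(x$Kxz), x$lambda,
              x$synthesis$J / x$synthesis$J_lqr, x$synthesis$dale_rel_err))
  invisible(x)
}

#' Simulate the gated thalamo-cortical loop
#'
#' Integrates the three-population nonlinear dynamics: cortex receives layer-4
#' feedback \eqn{K_{xz}\phi(z)} plus the steady input during preparation;
#' thalamus relays \eqn{K_{yx}\phi(x)} while the basal-ganglia gate is open
#' (disinhibition) and is silenced (\eqn{y = 0}) while closed; layer 4
#' integrates \eqn{K_{zy}\phi(y)} with time constant \code{tau_z}. At the go
#' cue the gate closes, the steady input is withdrawn, and the movement epoch
#' unfolds (with the condition-independent bump for ISN tasks); torques are
#' read out and the arm is simulated.
#'
#' @param circuit a \code{prepctrl_loop}.
#' @param prep_ms preparation duration (gate open), ms.
#' @param move_ms movement duration, ms.
#' @param pre_ms time simulated before preparation onset (gate closed), ms.
#' @param perturb optional photoinhibition spec: list with \code{units}
#'   (indices of cortical cells), \code{h} (input strength), \code{on},
#'   \code{off} (ms relative to preparation onset). May be a list of k such
#'   lists (one per condition).
#' @param x_star optional override of the desired initial states.
#' @param dt Euler step, ms.
#' @return list of class \code{prepctrl_looptraj}: \code{times} (ms,
#'   0 = preparation onset), state arrays \code{x}, \code{y}, \code{z}
#'   (units x time x conditions), \code{m} torques, \code{hand} paths,
#'   \code{endpoint_err_m}, epoch index vectors, and \code{go_ms}.
#' @export
simulate_gated_loop <- function(circuit, prep_ms = 600, move_ms = 800,
                                pre_ms = 100, perturb = NULL, x_star = NULL,
                                dt = 1) {
  task <- circuit$task; model <- task$model
  N <- model$N; NE <- model$n_exc
  if (is.null(x_star)) x_star <- task$x_star
  k <- ncol(x_star)
  u_star <- if (is.null(x_star) || identical(x_star, task$x_star)) {
    circuit$u_star
  } else {
    x_star - (model$W + circuit$K) %*% relu(x_star) - model$h_bar
  }
  nt <- floor((pre_ms + prep_ms + move_ms) / dt) + 1
  times <- (seq_len(nt) - 1) * dt - pre_ms
  go <- prep_ms
  ## the unit-coupled thalamic integration stage z drives cortex through
  ## Kfb = Kxz Kzy; the physical layer-4 rates are Kzy %*% z (non-negative
  ## along the loop, so the linear composition is exact)
  Kfb <- circuit$Kxz %*% circuit$Kzy
  h_move <- if (task$include_h) {
    ifelse(times >= go, transient_input(times, t_move = go), 0)
  } else rep(0, nt)
  pert_mat <- matrix(0, N, k)
  p_on <- p_off <- -1L
  if (!is.null(perturb)) {
    if (is.null(perturb$units)) {           # one spec per condition
      for (j in seq_len(k)) pert_mat[perturb[[j]]$units, j] <- perturb[[j]]$h
      p_on <- perturb[[1]]$on; p_off <- perturb[[1]]$off
    } else {
      pert_mat[perturb$units, ] <- perturb$h
      p_on <- perturb$on; p_off <- perturb$off
    }
    p_on <- as.integer(round((p_on + pre_ms) / dt))
    p_off <- as.integer(round((p_off + pre_ms) / dt))
  }
  sim <- loop_sim_cpp(model$W, model$h_bar, Kfb, circuit$Kyx, u_star,
                      matrix(model$x_sp, N, k), h_move, pert_mat,
                      p_on, p_off, model$tau, circuit$tau_y, circuit$tau_z,
                      dt, as.integer(round(pre_ms / dt)),
                      as.integer(round(prep_ms / dt)), nt)
  xs <- aperm(sim$x, c(1, 3, 2)); ys <- aperm(sim$y, c(1, 3, 2))
  zs <- aperm(sim$z, c(1, 3, 2))
  ## torques: zero during preparation, read out during movement
  m <- array(0, c(2, nt, k))
  imove <- which(times >= go)
  for (j in seq_len(k)) {
    m[, imove, j] <- task$C %*% relu(xs[, imove, j])
  }
  arm <- arm_simulate(m[, imove, , drop = FALSE], dt, task$targets$params)
  n_cmp <- min(length(imove), dim(task$targets$hand)[2])
  endpoint <- sqrt(colSums((arm$hand[, n_cmp, ] -
                              task$targets$hand[, n_cmp, ])^2))
  structure(list(times = times, x = xs, y = ys, z = zs, m = m,
                 hand = arm$hand, endpoint_err_m = max(endpoint),
                 endpoint_err = endpoint, go_ms = go, imove = imove,
                 dt = dt),
            class = "prepctrl_looptraj")
}

#' Re-optimize desired initial states for the gated loop
#'
#' After the gate closes, layer-4 activity decays with \code{tau_z} but keeps
#' injecting \eqn{K_{xz} K_{zy} z(t)} into cortex, perturbing the movement.
#' This re-optimizes each \eqn{x^*_k} (readout \code{C} held fixed, as the
#' feedback synthesis depends on it) so that the movement epoch including the
#' layer-4 decay transient reproduces the target torques. The adjoint
#' gradient flows through both the cortical rollout and the (closed-form)
#' layer-4 decay from its preparatory fixed point
#' \eqn{z^*(x^*) = K_{zy} K_{yx} \phi(x^*)}.
#'
#' @param circuit a \code{prepctrl_loop}.
#' @param dt_cal rollout step, ms.
#' @param maxit L-BFGS iteration cap.
#' @return the circuit with updated \code{task$x_star} and \code{u_star};
#'   diagnostics in \code{$refit}.
#' @export
refit_initial_states <- function(circuit, dt_cal = 1, maxit = 200) {
  task <- circuit$task; model <- task$model
  N <- model$N; k <- ncol(task$x_star); tau <- model$tau
  targets <- task$targets
  T_ms <- max(targets$times)
  t_grid <- seq(0, T_ms, by = dt_cal)
  nt <- length(t_grid); dts <- dt_cal / 1000
  h_vals <- if (task$include_h) transient_input(t_grid, t_move = 0) else rep(0, nt)
  m_star_grid <- targets$m_star[, match(t_grid, targets$times), , drop = FALSE]
  C <- task$C
  Kzyx <- circuit$Kzy %*% circuit$Kyx    # z* = Kzy Kyx phi(x*)
  Kfb <- circuit$Kxz
  ## discrete decay factor of the layer-4 Euler recursion, so that the
  ## refit model matches the gated simulation exactly at this step size
  decay <- (1 - dt_cal / circuit$tau_z)^(seq_along(t_grid) - 1)
  m_perm <- aperm(m_star_grid, c(1, 3, 2))
  h_vals <- as.numeric(h_vals)
  fn <- function(p) {
    refit_core_cpp(model$W, model$x_sp, C, matrix(p, N, k), m_perm, h_vals,
                   Kfb, Kzyx, decay, dt_cal, tau, dts, FALSE)$loss
  }
  gr <- function(p) {
    as.numeric(refit_core_cpp(model$W, model$x_sp, C, matrix(p, N, k),
                              m_perm, h_vals, Kfb, Kzyx, decay, dt_cal, tau,
                              dts, TRUE)$gXs)
  }
  opt <- stats::optim(as.numeric(task$x_star), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  Xs <- matrix(opt$par, N, k)
  circuit$task$x_star <- Xs
  circuit$u_star <- Xs - (model$W + circuit$K) %*% relu(Xs) - model$h_bar
  circuit$refit <- list(loss = opt$value, convergence = opt$convergence)
  circuit
}
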
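## Calibration of the motor readout and movement-specific initial conditions
## (and, for trainable classes, of the recurrent weights), plus normal
## "surrogate" networks obtained by similarity transformation.

## Projection matrix onto span(S) and its orthogonal complement applied to a
## row-space: C = C0 (I - Pi). M = S'S must be invertible.
proj_span <- function(S) {
  M <- crossprod(S)
  S %*% solve(M, t(S))
}

## Movement-epoch rollout used by the calibration loss: forward Euler on
## tau dx/dt = -x + W(phi(x) - phi(x_sp)) + x_sp + h(t), which makes x_sp a
## fixed point for any W (the background input h_bar is eliminated).
## X0: N x k. Returns N x nt x k array of activations.
calib_rollout <- function(W, x_sp, X0, h_vals, dt, tau, linear = FALSE) {
  N <- nrow(W); k <- ncol(X0); nt <- length(h_vals)
  phi <- if (linear) identity else relu
  r_sp <- phi(x_sp)
  X <- X0
  out <- array(NA_real_, c(N, nt, k))
  for (i in seq_len(nt)) {
    out[, i, ] <- X
    if (i == nt) break
    X <- X + (dt / tau) * (-X + W %*% (phi(X) - r_sp) + x_sp + h_vals[i])
  }
  out
}

## Calibration loss + gradients. Parameters:
##   C0E : 2 x NE free readout (E columns only; I columns of C are zero)
##   Xs  : N x k initial conditions
##   W   : recurrent matrix (fixed unless train_w)
## Loss (Eq.-16 form): mean_k int ||m_k - m*_k||^2 dt  +  ||C||^2/(2 NE)
## with m = C phi(x), C = [C0E (I - Pi_E), 0], Pi_E projecting onto the
## E-components of {x_sp, x*_1..k}.
calib_loss_grad <- function(C0E, Xs, W, model, m_star_grid, h_vals, dt,
                            linear = FALSE, train_w = FALSE,
                            with_grad = TRUE) {
  N <- model$N; NE <- model$n_exc; k <- ncol(Xs)
  tau <- model$tau; x_sp <- model$x_sp
  nt <- length(h_vals)
  dts <- dt / 1000                      # torque-error integral in seconds
  phi <- if (linear) identity else relu
  dphi <- if (linear) function(x) array(1, dim(x)) else function(x) (x > 0) * 1
  iE <- seq_len(NE)
  SE <- cbind(x_sp[iE], Xs[iE, , drop = FALSE])
  PiE <- proj_span(SE)
  CE <- C0E - C0E %*% PiE
  C <- cbind(CE, matrix(0, 2, N - NE))
  traj <- calib_rollout(W, x_sp, Xs, h_vals, dt, tau, linear)
  loss_m <- 0
  E_list <- vector("list", nt)
  for (i in seq_len(nt)) {
    e <- C %*% phi(traj[, i, ]) - m_star_grid[, i, ]
    E_list[[i]] <- e
    loss_m <- loss_m + sum(e^2) * dts
  }
  loss <- loss_m / k + sum(C^2) / (2 * NE)
  if (!with_grad) return(list(loss = loss, C = C))
  ## backward pass
  gC <- matrix(0, 2, N)
  lam <- matrix(0, N, k)
  gXs <- matrix(0, N, k)
  r_sp <- phi(x_sp)
  Wt <- t(W)
  gW <- if (train_w) matrix(0, N, N) else NULL
  for (i in nt:1) {
    Xi <- traj[, i, ]
    ri <- phi(Xi)
    e <- E_list[[i]]
    gC <- gC + (2 * dts / k) * e %*% t(ri)
    direct <- (2 * dts / k) * dphi(Xi) * crossprod(C, e)
    lam <- lam + direct
    if (i == 1) break
    ## propagate adjoint through step i-1 -> i
    Xp <- traj[, i - 1, ]
    if (train_w) {
      gW <- gW + (dt / tau) * lam %*% t(phi(Xp) - r_sp)
    }
    lam <- lam + (dt / tau) * (-lam + dphi(Xp) * (Wt %*% lam))
  }
  gXs <- lam
  gC <- gC + C / NE
  gCE <- gC[, iE, drop = FALSE]
  gC0E <- gCE - gCE %*% PiE
  ## gradient through the projection: dL/dS_E = (I-Pi)(G + G')S M^{-1}
  G <- -crossprod(C0E, gCE)
  M <- crossprod(SE)
  dS <- (diag(NE) - PiE) %*% (G + t(G)) %*% SE %*% solve(M)
  gXs[iE, ] <- gXs[iE, ] + dS[, -1, drop = FALSE]
  list(loss = loss, C = C, gC0E = gC0E, gXs = gXs, gW = gW)
}

## Internal pieces of the calibration optimizer ------------------------------

## Exact linear-regime alternation: for the linearized dynamics, the readout
## fit given the initial conditions and the initial-condition fit given the
## readout are both linear least-squares problems (solved in the eigenbasis
## of A). The deviation-fit ridge mu is adapted so that the largest
## ||x*-x_sp|| stays within `cap`, keeping the starting point in the
## near-linear regime. Returns list(C0E, Xs).
calib_lin_init <- function(model, m_star_grid, h_vals, t_grid, dt_cal, k,
                           cap = c(100, 220), rounds = 8) {
  N <- model$N; NE <- model$n_exc; iE <- seq_len(NE)
  tau <- model$tau; x_sp <- model$x_sp
  dts <- dt_cal / 1000; w <- dts / k
  A <- model$W - diag(N)
  fac <- eigen_factor(A)
  nt <- length(t_grid)
  ## response to the condition-independent bump (linear, Euler)
  q <- matrix(0, N, nt); qq <- rep(0, N)
  for (i in seq_len(nt - 1)) {
    qq <- qq + (dt_cal / tau) * (A %*% qq + h_vals[i])
    q[, i + 1] <- qq
  }
  prop_all <- function(Delta) {
    D_ <- fac$Vi %*% Delta
    out <- array(0, c(N, nt, k))
    for (i in seq_len(nt)) {
      out[, i, ] <- Re(fac$V %*% (exp(fac$values * t_grid[i] / tau) * D_))
    }
    out
  }
  Delta <- matrix(stats::rnorm(N * k, 0, 2), N, k)
  C0E <- NULL; mu <- 1e-5
  for (it in seq_len(rounds)) {
    SE <- cbind(x_sp[iE], (x_sp + Delta)[iE, ]); PiE <- proj_span(SE)
    P <- prop_all(Delta)
    G <- matrix(0, NE, NE); Bv <- matrix(0, 2, NE)
    for (i in seq_len(nt)) {
      z <- P[iE, i, ] + q[iE, i]; z <- z - PiE %*% z
      G <- G + w * tcrossprod(z)
      Bv <- Bv + w * m_star_grid[, i, ] %*% t(z)
    }
    C0E <- t(solve(G + diag(NE) / (2 * NE), t(Bv)))
    CE <- C0E - C0E %*% PiE; C <- cbind(CE, matrix(0, 2, N - NE))
    Pc <- diag(N) - crossprod(C, solve(tcrossprod(C), C))
    CV <- C %*% fac$V
    M2 <- matrix(0, N, N); rhs <- matrix(0, N, k)
    for (i in seq_len(nt)) {
      Ot <- Re((CV * rep(exp(fac$values * t_grid[i] / tau), each = 2)) %*%
                 fac$Vi) %*% Pc
      M2 <- M2 + dts * crossprod(Ot)
      rhs <- rhs + dts * crossprod(Ot, m_star_grid[, i, ] -
                                     as.numeric(C %*% q[, i]))
    }
    for (tries in 1:25) {
      Dn <- Pc %*% solve(M2 + mu * diag(N), rhs)
      mx <- max(sqrt(colSums(Dn^2)))
      if (mx > cap[2]) mu <- mu * 2 else if (mx < cap[1]) mu <- mu / 2 else break
    }
    Delta <- Dn
  }
  list(C0E = C0E, Xs = x_sp + Delta)
}

## Loss (data term via the compiled rollout + readout penalty) for a fully
## assembled readout C.
calib_loss_cpp <- function(model, C, Xs, m_perm, h_vals, dt_cal, NE,
                           linear = FALSE) {
  calib_core_cpp(model$W, model$x_sp, C, Xs, m_perm, h_vals, dt_cal,
                 model$tau, dt_cal / 1000, linear, FALSE, FALSE)$loss +
    sum(C^2) / (2 * NE)
}

## One block of guarded alternation: exact ridge re-fit of the readout on
## the current nonlinear trajectories (accepted only if the loss improves),
## followed by one damped Gauss-Newton step per condition on the initial
## states, constrained to the nullspace of C.
calib_gn_block <- function(state, model, m_star_grid, m_perm, h_vals,
                           t_grid, dt_cal, rounds) {
  N <- model$N; NE <- model$n_exc; iE <- seq_len(NE)
  k <- ncol(state$Xs); nt <- length(t_grid)
  x_sp <- model$x_sp
  dts <- dt_cal / 1000; w <- dts / k
  Bsp <- qr.Q(qr(cbind(x_sp[iE], diag(NE))))[, 2:NE]
  C <- state$C; Xs <- state$Xs; l_now <- state$loss
  lamLM <- state$lamLM
  if (is.null(lamLM)) lamLM <- rep(1e-2, k)
  for (round in seq_len(rounds)) {
    traj <- calib_rollout(model$W, x_sp, Xs, h_vals, dt_cal, model$tau)
    G <- matrix(0, NE - 1, NE - 1); Bv <- matrix(0, 2, NE - 1)
    for (i in seq_len(nt)) {
      z <- crossprod(Bsp, relu(matrix(traj[iE, i, ], NE, k)))
      G <- G + w * tcrossprod(z)
      Bv <- Bv + w * m_star_grid[, i, ] %*% t(z)
    }
    Chat <- t(solve(G + diag(NE - 1) / (2 * NE), t(Bv)))
    Cn <- cbind(Chat %*% t(Bsp), matrix(0, 2, N - NE))
    Pcn <- diag(N) - crossprod(Cn, solve(tcrossprod(Cn), Cn))
    Xn <- x_sp + Pcn %*% (Xs - x_sp)
    ln <- calib_loss_cpp(model, Cn, Xn, m_perm, h_vals, dt_cal, NE)
    if (ln < l_now) { C <- Cn; Xs <- Xn; l_now <- ln }
    Nc <- qr.Q(qr(t(C)), complete = TRUE)[, 3:N]
    for (j in seq_len(k)) {
      g <- gn_condition_cpp(model$W, x_sp, C, Xs[, j], m_star_grid[, , j],
                            h_vals, dt_cal, model$tau, w)
      Jh <- crossprod(Nc, g$JtJ %*% Nc); rh <- crossprod(Nc, g$Jtr)
      for (tries in 1:12) {
        deta <- tryCatch(solve(Jh + lamLM[j] * diag(diag(Jh) + 1e-10), -rh),
                         error = function(e) NULL)
        if (is.null(deta)) { lamLM[j] <- lamLM[j] * 10; next }
        Xtry <- Xs; Xtry[, j] <- Xs[, j] + Nc %*% deta
        ltry <- calib_loss_cpp(model, C, Xtry, m_perm, h_vals, dt_cal, NE)
        if (is.finite(ltry) && ltry < l_now) {
          Xs <- Xtry; l_now <- ltry; lamLM[j] <- lamLM[j] / 2
          break
        }
        lamLM[j] <- lamLM[j] * 10
      }
    }
  }
  list(C = C, Xs = Xs, loss = l_now, lamLM = lamLM)
}

## Joint L-BFGS refinement in the projection parameterization
## C = [C0E (I - Pi_E), 0] with Pi_E spanning the spontaneous state and all
## initial conditions; gradients through the projection are exact.
calib_polish <- function(C0E, Xs, model, m_star_grid, m_perm, h_vals,
                         dt_cal, maxit, linear = FALSE) {
  N <- model$N; NE <- model$n_exc; iE <- seq_len(NE); k <- ncol(Xs)
  x_sp <- model$x_sp
  evalfun <- function(p, grad = TRUE) {
    C0E <- matrix(p[seq_len(2 * NE)], 2, NE)
    Xs <- matrix(p[-seq_len(2 * NE)], N, k)
    SE <- cbind(x_sp[iE], Xs[iE, ]); M <- crossprod(SE)
    PiE <- SE %*% solve(M, t(SE))
    CE <- C0E - C0E %*% PiE
    C <- cbind(CE, matrix(0, 2, N - NE))
    out <- calib_core_cpp(model$W, x_sp, C, Xs, m_perm, h_vals, dt_cal,
                          model$tau, dt_cal / 1000, linear, grad, FALSE)
    loss <- out$loss + sum(C^2) / (2 * NE)
    if (!grad) return(loss)
    gC <- out$gC + C / NE
    gCE <- gC[, iE, drop = FALSE]; gC0E <- gCE - gCE %*% PiE
    G <- -crossprod(C0E, gCE)
    dS <- (diag(NE) - PiE) %*% (G + t(G)) %*% SE %*% solve(M)
    gXs <- out$gXs; gXs[iE, ] <- gXs[iE, ] + dS[, -1, drop = FALSE]
    list(loss = loss, grad = c(as.numeric(gC0E), as.numeric(gXs)))
  }
  last <- new.env()
  fn <- function(p) {
    o <- evalfun(p)
    assign("g", o$grad, last); assign("key", sum(p), last)
    o$loss
  }
  gr <- function(p) {
    if (!identical(get0("key", last), sum(p))) fn(p)
    get("g", last)
  }
  psc <- c(rep(0.02, 2 * NE), rep(1, N * k))
  opt <- stats::optim(c(as.numeric(C0E), as.numeric(Xs)), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e1,
                                     parscale = psc))
  C0E <- matrix(opt$par[seq_len(2 * NE)], 2, NE)
  Xs <- matrix(opt$par[-seq_len(2 * NE)], N, k)
  SE <- cbind(x_sp[iE], Xs[iE, ]); PiE <- proj_span(SE)
  CE <- C0E - C0E %*% PiE
  list(C0E = C0E, Xs = Xs, C = cbind(CE, matrix(0, 2, N - NE)),
       loss = opt$value)
}

#' Calibrate readout and initial conditions for a fixed network
#'
#' Optimizes the torque readout \code{C} and the movement-specific initial
#' conditions \code{x*_k} so that the autonomous movement-epoch dynamics of
#' the network reproduce the target torques: the loss is the mean integrated
#' squared torque error over conditions plus a Frobenius penalty
#' \eqn{\|C\|^2 / (2 N_E)}. The readout is parameterized so that (i) only
#' excitatory neurons contribute (last \eqn{N_I} columns are zero) and (ii)
#' its nullspace contains the spontaneous state and all \code{x*_k} by
#' construction, so no torque is produced at rest or at the end of
#' preparation.
#'
#' The optimizer combines an exact linear-regime alternating least-squares
#' initialization, cycles of damped Gauss-Newton steps (readout re-fit by
#' ridge regression, per-condition initial-state steps with exact forward
#' sensitivities) interleaved with joint L-BFGS refinement, and a final
#' refinement at successively finer integration steps so that the solution
#' is consistent with the 1 ms step used by all downstream simulations.
#'
#' @param model a \code{prepctrl_network}.
#' @param targets a \code{\link{target_reaches}} object with torques inverted.
#' @param dt_cal rollout step of the main optimization stage, ms.
#' @param include_h include the condition-independent movement-epoch bump
#'   \code{h(t)} in the rollout (default: \code{TRUE} for the ISN class, as
#'   in the main model; other classes exclude it).
#' @param cycles number of Gauss-Newton + L-BFGS cycles.
#' @param gn_rounds Gauss-Newton rounds per cycle.
#' @param maxit L-BFGS iterations per cycle.
#' @param refine_dts integration steps (ms) of the final refinement stages.
#' @param refine_rounds Gauss-Newton rounds per refinement stage.
#' @param init_sd standard deviation of the random initialization (used
#'   when the linear initialization is unavailable, e.g. chaotic networks).
#' @param linear calibrate against linearized dynamics (analytical checks).
#' @param seed RNG seed for the initialization.
#' @return object of class \code{prepctrl_task}: \code{C}, \code{x_star},
#'   the model and targets, and replay diagnostics.
#' @export
calibrate <- function(model, targets, dt_cal = 5, include_h = NULL,
                      cycles = 3, gn_rounds = 15, maxit = 400,
                      refine_dts = c(2, 1), refine_rounds = c(3, 2),
                      init_sd = 2, linear = FALSE, seed = 0) {
  if (is.null(targets$m_star)) stop("calibrate: run invert_torques(targets) first")
  if (is.null(include_h)) include_h <- model$class == "isn"
  N <- model$N; k <- dim(targets$m_star)[3]
  NEeff <- if (model$n_inh > 0) model$n_exc else N
  model_eff <- model
  model_eff$n_exc <- NEeff                # non-Dale classes: all units read out
  T_ms <- max(targets$times)
  grids <- function(dt) {
    t_grid <- seq(0, T_ms, by = dt)
    h_vals <- if (include_h) transient_input(t_grid, t_move = 0)
              else rep(0, length(t_grid))
    msg <- targets$m_star[, match(t_grid, targets$times), , drop = FALSE]
    list(t_grid = t_grid, h_vals = as.numeric(h_vals), msg = msg,
         m_perm = aperm(msg, c(1, 3, 2)))
  }
  g <- grids(dt_cal)
  set.seed(seed)
  stable <- spectral_abscissa(model$W - diag(N)) < 0 && !linear
  if (stable) {
    init <- calib_lin_init(model_eff, g$msg, g$h_vals, g$t_grid, dt_cal, k)
  } else {
    init <- list(C0E = matrix(stats::rnorm(2 * NEeff, 0, 1e-2), 2, NEeff),
                 Xs = model$x_sp + matrix(stats::rnorm(N * k, 0, init_sd),
                                          N, k))
  }
  ## assemble C from the initial parameterization
  iE <- seq_len(NEeff)
  SE <- cbind(model$x_sp[iE], init$Xs[iE, ]); PiE <- proj_span(SE)
  C <- cbind(init$C0E - init$C0E %*% PiE, matrix(0, 2, N - NEeff))
  state <- list(C = C, Xs = init$Xs,
                loss = calib_loss_cpp(model_eff, C, init$Xs, g$m_perm,
                                      g$h_vals, dt_cal, NEeff, linear),
                lamLM = NULL)
  for (cyc in seq_len(cycles)) {
    if (!linear) {
      state <- calib_gn_block(state, model_eff, g$msg, g$m_perm, g$h_vals,
                              g$t_grid, dt_cal, gn_rounds)
    }
    pol <- calib_polish(state$C[, iE, drop = FALSE], state$Xs, model_eff,
                        g$msg, g$m_perm, g$h_vals, dt_cal, maxit, linear)
    state$C <- pol$C; state$Xs <- pol$Xs; state$loss <- pol$loss
  }
  ## refinement at finer steps for discretization-consistent solutions
  if (!linear) {
    for (s in seq_along(refine_dts)) {
      gf <- grids(refine_dts[s])
      state$loss <- calib_loss_cpp(model_eff, state$C, state$Xs, gf$m_perm,
                                   gf$h_vals, refine_dts[s], NEeff)
      state <- calib_gn_block(state, model_eff, gf$msg, gf$m_perm, gf$h_vals,
                              gf$t_grid, refine_dts[s], refine_rounds[s])
    }
  }
  task <- structure(list(C = state$C, x_star = state$Xs, model = model,
                         targets = targets, include_h = include_h,
                         loss = state$loss, linear = linear,
                         convergence = 0L),
                    class = "prepctrl_task")
  task$replay <- torque_replay(task)
  task
}

#' @export
print.prepctrl_task <- function(x, ...) {
  cat(sprintf("<prepctrl_task: %d conditions, loss %.3g, torque replay RMS %.1f%% of target>\n",
              ncol(x$x_star), x$loss, 100 * x$replay$rms_ratio))
  invisible(x)
}

#' Replay a calibrated task through the nonlinear model
#'
#' Simulates the movement epoch from each calibrated initial condition at
#' 1 ms resolution, reads out torques, and drives the arm.
#'
#' @param task a \code{prepctrl_task}.
#' @param x0 optional N x k matrix of initial states (defaults to
#'   \code{task$x_star}).
#' @return list: torque traces \code{m} (2 x nt x k), relative torque error
#'   \code{rms_ratio}, hand paths and worst-case \code{endpoint_err_m}.
#' @export
torque_replay <- function(task, x0 = NULL) {
  model <- task$model; targets <- task$targets
  if (is.null(x0)) x0 <- task$x_star
  T_ms <- max(targets$times)
  h_fn <- if (task$include_h) function(t) transient_input(t, t_move = 0) else NULL
  traj <- simulate(model, T_ms, x0 = x0, h_fn = h_fn, dt = targets$dt,
                   linear = isTRUE(task$linear))
  k <- ncol(x0); nt <- length(traj$times)
  m <- array(NA_real_, c(2, nt, k))
  for (j in seq_len(k)) m[, , j] <- task$C %*% traj$rates[, , j]
  rms_ratio <- sqrt(sum((m - targets$m_star)^2) / sum(targets$m_star^2))
  arm <- arm_simulate(m, targets$dt, targets$params)
  endpoint <- sqrt(colSums((arm$hand[, nt, ] - targets$hand[, nt, ])^2))
  list(m = m, rms_ratio = rms_ratio, hand = arm$hand,
       endpoint_err_m = max(endpoint), traj = traj)
}

#' Calibrate a trainable network class (full or low-rank)
#'
#' Like \code{\link{calibrate}}, but also optimizes the recurrent
#' connectivity: every element of \code{W} for \code{"full"} networks
#' (regularized by \eqn{\|W\|^2/N^2}), or the rank-constrained factors
#' \code{u, v} of \eqn{W = W_{base} + u v^T} for \code{"lowrank"} networks
#' (regularized by \eqn{(\|u\|^2 + \|v\|^2)/(5N)}). The condition-independent
#' input \code{h(t)} is excluded during training for these classes.
#'
#' @param model a \code{prepctrl_network} of class \code{"full"} (any
#'   network; its \code{W} is re-optimized) or \code{"lowrank"}.
#' @param targets a \code{\link{target_reaches}} object with torques inverted.
#' @param dt_cal,maxit,init_sd,seed as in \code{\link{calibrate}}.
#' @return list with the updated \code{model} and the fitted
#'   \code{prepctrl_task}.
#' @export
calibrate_trained <- function(model, targets, dt_cal = 5, maxit = 600,
                              init_sd = 2, seed = 0) {
  if (is.null(targets$m_star)) stop("run invert_torques(targets) first")
  lowrank <- identical(model$class, "lowrank")
  N <- model$N; k <- dim(targets$m_star)[3]
  T_ms <- max(targets$times)
  t_grid <- seq(0, T_ms, by = dt_cal)
  h_vals <- rep(0, length(t_grid))         # h(t) excluded for trained classes
  m_star_grid <- targets$m_star[, match(t_grid, targets$times), , drop = FALSE]
  set.seed(seed)
  C0E <- matrix(stats::rnorm(2 * N, 0, 1e-2), 2, N)
  Xs <- model$x_sp + matrix(stats::rnorm(N * k, 0, init_sd), N, k)
  model_eff <- model; model_eff$n_exc <- N
  nC <- 2 * N; nX <- N * k
  rank <- if (lowrank) model$rank else 0
  unpack <- function(p) {
    out <- list(C0E = matrix(p[seq_len(nC)], 2, N),
                Xs = matrix(p[nC + seq_len(nX)], N, k))
    rest <- p[-(seq_len(nC + nX))]
    if (lowrank) {
      out$u <- matrix(rest[seq_len(N * rank)], N, rank)
      out$v <- matrix(rest[N * rank + seq_len(N * rank)], N, rank)
      out$W <- model$W_base + out$u %*% t(out$v)
    } else {
      out$W <- matrix(rest, N, N)
    }
    out
  }
  regular <- function(q) {
    if (lowrank) (sum(q$u^2) + sum(q$v^2)) / (5 * N) else sum(q$W^2) / N^2
  }
  fn <- function(p) {
    q <- unpack(p)
    calib_loss_grad(q$C0E, q$Xs, q$W, model_eff, m_star_grid, h_vals, dt_cal,
                    with_grad = FALSE)$loss + regular(q)
  }
  gr <- function(p) {
    q <- unpack(p)
    out <- calib_loss_grad(q$C0E, q$Xs, q$W, model_eff, m_star_grid, h_vals,
                           dt_cal, train_w = TRUE)
    gW <- out$gW
    if (lowrank) {
      gu <- gW %*% q$v + 2 * q$u / (5 * N)
      gv <- t(gW) %*% q$u + 2 * q$v / (5 * N)
      c(as.numeric(out$gC0E), as.numeric(out$gXs), as.numeric(gu),
        as.numeric(gv))
    } else {
      c(as.numeric(out$gC0E), as.numeric(out$gXs),
        as.numeric(gW + 2 * q$W / N^2))
    }
  }
  par0 <- c(as.numeric(C0E), as.numeric(Xs),
            if (lowrank) c(as.numeric(model$u), as.numeric(model$v))
            else as.numeric(model$W))
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e3))
  q <- unpack(opt$par)
  model$W <- q$W
  model$h_bar <- as.numeric(model$x_sp - q$W %*% relu(model$x_sp))
  if (lowrank) { model$u <- q$u; model$v <- q$v }
  final <- calib_loss_grad(q$C0E, q$Xs, q$W, model_eff, m_star_grid, h_vals,
                           dt_cal, with_grad = FALSE)
  task <- structure(list(C = final$C, x_star = q$Xs, model = model,
                         targets = targets, include_h = FALSE,
                         loss = final$loss, linear = FALSE,
                         convergence = opt$convergence),
                    class = "prepctrl_task")
  task$replay <- torque_replay(task)
  list(model = model, task = task)
}

#' Normal surrogate of a calibrated network
#'
#' Applies the similarity transformation that block-diagonalizes
#' \eqn{A = W - I} into real 1x1 / 2x2 rotation blocks, yielding a normal
#' state matrix \eqn{\tilde A} with identical linear input-output behavior:
#' \eqn{\tilde C e^{t\tilde A}\tilde x^* = C e^{tA} x^*}. The transform is
#' rescaled so that \eqn{\sum_k \|\tilde x^*_k - x_{sp}\|^2 =
#' \sum_k \|x^*_k - x_{sp}\|^2}.
#'
#' @param task a \code{prepctrl_task}.
#' @return list of class \code{prepctrl_surrogate}: \code{T_mat},
#'   \code{A_tilde}, \code{C_tilde}, \code{x_star_tilde}, \code{x_sp},
#'   \code{h_bar_tilde} \eqn{= -\tilde A x_{sp}} and the source \code{task}.
#' @export
make_normal_surrogate <- function(task) {
  W <- task$model$W; N <- nrow(W)
  A <- W - diag(N)
  e <- eigen(A)
  Tm <- matrix(NA_real_, N, N)
  j <- 1
  used <- rep(FALSE, N)
  for (i in seq_len(N)) {
    if (used[i]) next
    lam <- e$values[i]
    if (abs(Im(lam)) < 1e-12) {
      Tm[, j] <- Re(e$vectors[, i]); used[i] <- TRUE; j <- j + 1
    } else {
      Tm[, j] <- Re(e$vectors[, i]); Tm[, j + 1] <- Im(e$vectors[, i])
      used[i] <- TRUE
      ## mark the conjugate partner as used
      partner <- which(!used & abs(e$values - Conj(lam)) < 1e-9)[1]
      if (!is.na(partner)) used[partner] <- TRUE
      j <- j + 2
    }
    if (j > N) break
  }
  x_sp <- task$model$x_sp
  Ti <- solve(Tm)
  dX <- task$x_star - x_sp
  dXt <- Ti %*% dX
  alpha <- sqrt(sum(dXt^2) / sum(dX^2))    # T <- alpha T preserves total norm
  Tm <- Tm * alpha
  Ti <- Ti / alpha
  A_tilde <- Ti %*% A %*% Tm
  structure(list(T_mat = Tm, A_tilde = A_tilde, C_tilde = task$C %*% Tm,
                 x_star_tilde = x_sp + Ti %*% dX, x_sp = x_sp,
                 h_bar_tilde = as.numeric(-A_tilde %*% x_sp), task = task),
            class = "prepctrl_surrogate")
}

#' Simulate a surrogate network's linear dynamics
#'
#' @param surr a \code{prepctrl_surrogate}.
#' @param T_ms duration (ms).
#' @param x0 initial state vector or matrix (defaults to
#'   \code{x_star_tilde}).
#' @param dt Euler step, ms.
#' @return \code{prepctrl_trajectory} of the linear dynamics
#'   \eqn{\tau\dot x = \tilde A x + \tilde h}.
#' @export
simulate_surrogate <- function(surr, T_ms, x0 = NULL, dt = 1) {
  if (is.null(x0)) x0 <- surr$x_star_tilde
  X <- if (is.matrix(x0)) x0 else matrix(x0, ncol = 1)
  tau <- surr$task$model$tau
  nt <- floor(T_ms / dt) + 1
  out <- array(NA_real_, c(nrow(X), nt, ncol(X)))
  for (i in seq_len(nt)) {
    out[, i, ] <- X
    if (i == nt) break
    X <- X + (dt / tau) * (surr$A_tilde %*% X + surr$h_bar_tilde)
  }
  structure(list(times = (seq_len(nt) - 1) * dt, x = out, rates = out,
                 dt = dt, linear = TRUE),
            class = "prepctrl_trajectory")
}
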
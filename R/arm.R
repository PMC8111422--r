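## Planar two-link arm: kinematics, dynamics, target reach construction, and
## inversion of the equations of motion for the torques that realize a target
## hand path.

#' Two-link arm parameters
#'
#' Link geometry, inertia and joint friction of the planar arm, plus the
#' resting joint angles. Defaults follow the standard parameterization used
#' for center-out reaching (lengths in m, masses in kg, inertia in kg m^2,
#' damping in N m s).
#'
#' @param L1,L2 link lengths (0.30, 0.33 m).
#' @param M1,M2 link masses (1.4, 1.0 kg).
#' @param D2 distance of the lower-link center of mass from the elbow (0.16 m).
#' @param I1,I2 link moments of inertia (0.025, 0.045 kg m^2).
#' @param B 2x2 joint damping matrix.
#' @param theta_init resting joint angles, degrees (10, 143.54): the hand then
#'   rests at approximately (0, 0.2) m from the shoulder.
#' @return list of class \code{prepctrl_arm} with derived inertia constants
#'   \code{a1 = I1 + I2 + M2 L1^2}, \code{a2 = M2 L1 D2}, \code{a3 = I2}.
#' @export
arm_params <- function(L1 = 0.30, L2 = 0.33, M1 = 1.4, M2 = 1.0, D2 = 0.16,
                       I1 = 0.025, I2 = 0.045,
                       B = matrix(c(0.05, 0.025, 0.025, 0.05), 2, 2),
                       theta_init = c(10, 143.54)) {
  structure(list(L1 = L1, L2 = L2, M1 = M1, M2 = M2, D2 = D2, I1 = I1,
                 I2 = I2, B = B, theta_init_deg = theta_init,
                 theta_init = theta_init * pi / 180,
                 a1 = I1 + I2 + M2 * L1^2, a2 = M2 * L1 * D2, a3 = I2),
            class = "prepctrl_arm")
}

#' Hand position from joint angles
#'
#' Forward kinematics \eqn{y = (L_1 \cos\theta_1 + L_2 \cos(\theta_1+\theta_2),
#' \ L_1 \sin\theta_1 + L_2 \sin(\theta_1+\theta_2))}.
#'
#' @param theta joint angles in radians: length-2 vector, or 2 x k matrix for
#'   k configurations.
#' @param params an \code{\link{arm_params}} object.
#' @return hand coordinates (m): length-2 vector or 2 x k matrix.
#' @export
hand_position <- function(theta, params = arm_params()) {
  th <- if (is.matrix(theta)) theta else matrix(theta, 2)
  out <- rbind(params$L1 * cos(th[1, ]) + params$L2 * cos(th[1, ] + th[2, ]),
               params$L1 * sin(th[1, ]) + params$L2 * sin(th[1, ] + th[2, ]))
  if (!is.matrix(theta)) out <- drop(out)
  out
}

## Inverse kinematics: joint angles for a hand target (elbow branch chosen to
## match the positive resting elbow angle).
hand_to_angles <- function(xy, params = arm_params()) {
  p <- if (is.matrix(xy)) xy else matrix(xy, 2)
  r2 <- colSums(p^2)
  c2 <- (r2 - params$L1^2 - params$L2^2) / (2 * params$L1 * params$L2)
  if (any(c2 < -1 - 1e-9 | c2 > 1 + 1e-9)) stop("hand_to_angles: target out of reach")
  th2 <- acos(pmin(pmax(c2, -1), 1))
  th1 <- atan2(p[2, ], p[1, ]) -
    atan2(params$L2 * sin(th2), params$L1 + params$L2 * cos(th2))
  out <- rbind(th1, th2)
  if (!is.matrix(xy)) out <- drop(out)
  out
}

## Inertia matrix entries and Coriolis/centripetal vector, vectorized over
## configurations. theta, omega: 2 x k.
arm_inertia <- function(theta2, params) {
  c2 <- cos(theta2)
  a <- params$a1 + 2 * params$a2 * c2
  b <- params$a3 + params$a2 * c2
  list(a = a, b = b, d = rep(params$a3, length(theta2)),
       det = a * params$a3 - b^2)
}

arm_coriolis <- function(theta2, omega, params) {
  s2 <- sin(theta2)
  rbind(-params$a2 * s2 * omega[2, ] * (2 * omega[1, ] + omega[2, ]),
        params$a2 * s2 * omega[1, ]^2)
}

#' One forward-Euler step of the arm dynamics
#'
#' Euler update of \eqn{M(\theta)\ddot\theta + X(\theta,\dot\theta) +
#' B\dot\theta = m}.
#'
#' @param state list with \code{theta} (2 x k, rad) and \code{omega}
#'   (2 x k, rad/s).
#' @param torque 2 x k torque matrix (N m).
#' @param dt time step, ms.
#' @param params an \code{\link{arm_params}} object.
#' @return updated state list.
#' @export
arm_step <- function(state, torque, dt = 1, params = arm_params()) {
  th <- state$theta; om <- state$omega
  if (!is.matrix(th)) { th <- matrix(th, 2); om <- matrix(om, 2) }
  if (!is.matrix(torque)) torque <- matrix(torque, 2)
  dts <- dt / 1000
  Mi <- arm_inertia(th[2, ], params)
  if (any(Mi$det <= 0)) stop("arm_step: singular inertia matrix")
  w <- torque - arm_coriolis(th[2, ], om, params) - params$B %*% om
  acc <- rbind((Mi$d * w[1, ] - Mi$b * w[2, ]) / Mi$det,
               (-Mi$b * w[1, ] + Mi$a * w[2, ]) / Mi$det)
  list(theta = th + dts * om, omega = om + dts * acc)
}

#' Simulate the arm under a torque time course
#'
#' @param torques 2 x nt x k array (or 2 x nt matrix for one condition) of
#'   torques on a regular grid with step \code{dt} ms.
#' @param dt time step, ms.
#' @param params an \code{\link{arm_params}} object.
#' @param state0 optional initial state (defaults to rest, zero velocity).
#' @return list with \code{theta}, \code{omega} (2 x nt x k), \code{hand}
#'   (2 x nt x k hand paths, m) and \code{times} (ms).
#' @export
arm_simulate <- function(torques, dt = 1, params = arm_params(),
                         state0 = NULL) {
  if (length(dim(torques)) == 2) torques <- array(torques, c(2, ncol(torques), 1))
  nt <- dim(torques)[2]; k <- dim(torques)[3]
  if (is.null(state0)) {
    state0 <- list(theta = matrix(params$theta_init, 2, k),
                   omega = matrix(0, 2, k))
  }
  th <- array(NA_real_, c(2, nt, k)); om <- array(NA_real_, c(2, nt, k))
  st <- state0
  for (i in seq_len(nt)) {
    th[, i, ] <- st$theta; om[, i, ] <- st$omega
    if (i == nt) break
    st <- arm_step(st, torques[, i, , drop = TRUE], dt, params)
  }
  hand <- array(NA_real_, c(2, nt, k))
  for (j in seq_len(k)) hand[, , j] <- hand_position(th[, , j], params)
  list(theta = th, omega = om, hand = hand, times = (seq_len(nt) - 1) * dt)
}

## Kinetic energy 0.5 * omega' M(theta) omega, vectorized over conditions.
arm_kinetic_energy <- function(theta, omega, params = arm_params()) {
  Mi <- arm_inertia(theta[2, ], params)
  0.5 * (Mi$a * omega[1, ]^2 + 2 * Mi$b * omega[1, ] * omega[2, ] +
           Mi$d * omega[2, ]^2)
}

#' Target center-out reaches
#'
#' Builds straight target hand paths of length \code{d} from the resting hand
#' position into the given directions, with the common bell-shaped speed
#' profile \eqn{v(t) = v_0 (t/\tau)^2 \exp(-\frac{1}{2}(t/\tau)^2)}. The peak
#' scaling \eqn{v_0 = d / (\tau\sqrt{\pi/2})} makes the total path length
#' equal \code{d}.
#'
#' @param angles_deg reach directions in degrees (default \code{36*(i-2)},
#'   i = 1..8).
#' @param d reach distance, m (0.20).
#' @param tau_reach speed-profile time constant, ms (120).
#' @param T_ms time horizon, ms (1000).
#' @param dt grid step, ms.
#' @param params an \code{\link{arm_params}} object.
#' @return object of class \code{prepctrl_reaches}: target hand paths
#'   \code{hand} (2 x nt x k), target joint angles \code{theta}, speeds,
#'   \code{v0}, grid \code{times}, and (once \code{\link{invert_torques}} has
#'   run) target torques \code{m_star}.
#' @export
target_reaches <- function(angles_deg = 36 * ((1:8) - 2), d = 0.20,
                           tau_reach = 120, T_ms = 1000, dt = 1,
                           params = arm_params()) {
  nt <- floor(T_ms / dt) + 1
  times <- (seq_len(nt) - 1) * dt
  tau_s <- tau_reach / 1000
  v0 <- d / (tau_s * sqrt(pi / 2))          # m/s
  w <- (times / tau_reach)
  speed <- v0 * w^2 * exp(-w^2 / 2)          # m/s
  ## arc length s(t) = d * [erf(w/sqrt(2)) - w exp(-w^2/2) / sqrt(pi/2)]
  s_t <- d * ((2 * stats::pnorm(w) - 1) - w * exp(-w^2 / 2) / sqrt(pi / 2))
  p0 <- hand_position(params$theta_init, params)
  k <- length(angles_deg)
  hand <- array(NA_real_, c(2, nt, k))
  theta <- array(NA_real_, c(2, nt, k))
  for (j in seq_len(k)) {
    a <- angles_deg[j] * pi / 180
    hand[, , j] <- rbind(p0[1] + cos(a) * s_t, p0[2] + sin(a) * s_t)
    theta[, , j] <- hand_to_angles(hand[, , j], params)
  }
  structure(list(angles_deg = angles_deg, d = d, tau_reach = tau_reach,
                 v0 = v0, times = times, dt = dt, speed = speed,
                 arc_length = s_t, hand = hand, theta = theta,
                 params = params, m_star = NULL),
            class = "prepctrl_reaches")
}

#' @export
print.prepctrl_reaches <- function(x, ...) {
  cat(sprintf("<prepctrl_reaches: %d reaches of %g cm, tau=%g ms, v0=%.3f m/s, torques %s>\n",
              length(x$angles_deg), 100 * x$d, x$tau_reach, x$v0,
              if (is.null(x$m_star)) "not yet inverted" else "inverted"))
  invisible(x)
}

## Loss and adjoint gradient for torque inversion: squared hand-path error
## integrated over time plus a roughness penalty on the torque time course.
## m_free: 2 x (nt-1) x k (torques at steps 2..nt; step 1 is clamped to zero).
## All per-condition scalars are length-k vectors.
torque_loss_grad <- function(m_free, targets, rho, with_grad = TRUE) {
  params <- targets$params
  nt <- length(targets$times); k <- dim(targets$hand)[3]
  dts <- targets$dt / 1000
  m <- array(0, c(2, nt, k))
  m[, 2:nt, ] <- m_free
  a2 <- params$a2; B <- params$B
  th <- matrix(params$theta_init, 2, k); om <- matrix(0, 2, k)
  ths <- array(NA_real_, c(2, nt, k)); oms <- array(NA_real_, c(2, nt, k))
  loss_path <- 0
  ## forward
  for (i in seq_len(nt)) {
    ths[, i, ] <- th; oms[, i, ] <- om
    e <- hand_position(th, params) - targets$hand[, i, ]
    loss_path <- loss_path + sum(e^2) * dts
    if (i == nt) break
    st <- arm_step(list(theta = th, omega = om), m[, i, ], targets$dt, params)
    th <- st$theta; om <- st$omega
  }
  dm <- (m[, 2:nt, , drop = FALSE] - m[, 1:(nt - 1), , drop = FALSE]) / dts
  loss_rough <- rho * sum(dm^2) / (nt - 1)
  loss <- (loss_path + loss_rough) / k
  if (!with_grad) return(list(loss = loss))
  ## backward (adjoint of the Euler recursion)
  g_m <- array(0, c(2, nt, k))
  lth <- matrix(0, 2, k); lom <- matrix(0, 2, k)
  for (i in nt:1) {
    th <- ths[, i, , drop = TRUE]; om <- oms[, i, , drop = TRUE]
    th <- matrix(th, 2, k); om <- matrix(om, 2, k)
    ## direct loss term at step i: d/dtheta of |hand(theta) - target|^2 dts
    e <- hand_position(th, params) - targets$hand[, i, ]
    s1 <- sin(th[1, ]); c1 <- cos(th[1, ])
    s12 <- sin(th[1, ] + th[2, ]); c12 <- cos(th[1, ] + th[2, ])
    J11 <- -params$L1 * s1 - params$L2 * s12; J12 <- -params$L2 * s12
    J21 <- params$L1 * c1 + params$L2 * c12;  J22 <- params$L2 * c12
    gth <- rbind(2 * dts * (J11 * e[1, ] + J21 * e[2, ]),
                 2 * dts * (J12 * e[1, ] + J22 * e[2, ]))
    lth <- lth + gth
    if (i == 1) break
    ## propagate through step i-1 -> i
    thp <- matrix(ths[, i - 1, ], 2, k); omp <- matrix(oms[, i - 1, ], 2, k)
    c2 <- cos(thp[2, ]); s2 <- sin(thp[2, ])
    a <- params$a1 + 2 * a2 * c2; b <- params$a3 + a2 * c2; d0 <- params$a3
    det <- a * d0 - b^2
    X <- arm_coriolis(thp[2, ], omp, params)
    w <- m[, i - 1, ] - X - B %*% omp
    w <- matrix(w, 2, k)
    acc1 <- (d0 * w[1, ] - b * w[2, ]) / det
    acc2 <- (-b * w[1, ] + a * w[2, ]) / det
    ## partials wrt theta2
    da <- -2 * a2 * s2; db <- -a2 * s2
    ddet <- d0 * da - 2 * b * db
    dX1 <- -a2 * c2 * omp[2, ] * (2 * omp[1, ] + omp[2, ])
    dX2 <- a2 * c2 * omp[1, ]^2
    dw1 <- -dX1; dw2 <- -dX2
    dacc1_dth2 <- (d0 * dw1 - db * w[2, ] - b * dw2) / det - acc1 * ddet / det
    dacc2_dth2 <- (-db * w[1, ] - b * dw1 + da * w[2, ] + a * dw2) / det -
      acc2 * ddet / det
    ## partials wrt omega: dacc/dom = Minv %*% (-dX/dom - B)
    dX1_o1 <- -2 * a2 * s2 * omp[2, ]
    dX1_o2 <- -2 * a2 * s2 * (omp[1, ] + omp[2, ])
    dX2_o1 <- 2 * a2 * s2 * omp[1, ]
    dX2_o2 <- rep(0, k)
    dw1_o1 <- -dX1_o1 - B[1, 1]; dw1_o2 <- -dX1_o2 - B[1, 2]
    dw2_o1 <- -dX2_o1 - B[2, 1]; dw2_o2 <- -dX2_o2 - B[2, 2]
    dacc1_o1 <- (d0 * dw1_o1 - b * dw2_o1) / det
    dacc1_o2 <- (d0 * dw1_o2 - b * dw2_o2) / det
    dacc2_o1 <- (-b * dw1_o1 + a * dw2_o1) / det
    dacc2_o2 <- (-b * dw1_o2 + a * dw2_o2) / det
    dtse <- dts
    ## adjoint updates: state (th, om) at i-1; lth/lom currently hold
    ## adjoints of state at i
    lth_new <- rbind(lth[1, ],
                     lth[2, ] + dtse * (dacc1_dth2 * lom[1, ] +
                                          dacc2_dth2 * lom[2, ]))
    lom_new <- rbind(dtse * lth[1, ] + lom[1, ] +
                       dtse * (dacc1_o1 * lom[1, ] + dacc2_o1 * lom[2, ]),
                     dtse * lth[2, ] + lom[2, ] +
                       dtse * (dacc1_o2 * lom[1, ] + dacc2_o2 * lom[2, ]))
    ## gradient wrt m_{i-1}: dts * Minv^T lom  (Minv symmetric)
    g_m[1, i - 1, ] <- dtse * ((d0 * lom[1, ] - b * lom[2, ]) / det)
    g_m[2, i - 1, ] <- dtse * ((-b * lom[1, ] + a * lom[2, ]) / det)
    lth <- lth_new; lom <- lom_new
  }
  ## roughness gradient: rho * 2 dm/dt differenced back, on the free part
  g_rough <- array(0, c(2, nt, k))
  g_rough[, 2:nt, ] <- g_rough[, 2:nt, , drop = FALSE] +
    2 * rho * dm / dts / (nt - 1)
  g_rough[, 1:(nt - 1), ] <- g_rough[, 1:(nt - 1), , drop = FALSE] -
    2 * rho * dm / dts / (nt - 1)
  g <- (g_m + g_rough) / k
  list(loss = loss, grad = g[, 2:nt, , drop = FALSE])
}

#' Invert the arm dynamics for target torques
#'
#' Solves for the torque time courses \eqn{m^*(t)} that reproduce the target
#' hand paths, by backpropagating through the Euler-discretized equations of
#' motion to minimize the integrated squared hand-path error plus a roughness
#' penalty (mean squared torque gradient). Initial torques at t = 0 are
#' structurally clamped to zero. The optimizer is initialized from the
#' discrete-consistent inverse-dynamics solution, so few refinement
#' iterations are needed.
#'
#' @param targets a \code{\link{target_reaches}} object.
#' @param rho roughness-penalty weight (default \code{1e-12}; see vignette).
#' @param maxit L-BFGS iteration cap.
#' @return the \code{targets} object with \code{m_star} (2 x nt x k torques)
#'   and \code{inversion} diagnostics (final loss, replay RMS error in m)
#'   filled in.
#' @export
invert_torques <- function(targets, rho = 1e-12, maxit = 100) {
  params <- targets$params
  nt <- length(targets$times); k <- dim(targets$hand)[3]
  dts <- targets$dt / 1000
  ## discrete-consistent inverse dynamics along the target angle trajectories
  m0 <- array(0, c(2, nt, k))
  for (j in seq_len(k)) {
    th <- targets$theta[, , j]
    omd <- cbind((th[, 2:nt] - th[, 1:(nt - 1)]) / dts, c(0, 0))
    for (i in 1:(nt - 1)) {
      Mi <- arm_inertia(th[2, i], params)
      accd <- if (i < nt - 1) (omd[, i + 1] - omd[, i]) / dts else c(0, 0)
      Mm <- matrix(c(Mi$a, Mi$b, Mi$b, Mi$d), 2, 2)
      m0[, i, j] <- Mm %*% accd +
        arm_coriolis(th[2, i], matrix(omd[, i], 2, 1), params) +
        params$B %*% omd[, i]
    }
  }
  m0[, 1, ] <- 0
  par0 <- as.numeric(m0[, 2:nt, , drop = FALSE])
  fn <- function(p) {
    torque_loss_grad(array(p, c(2, nt - 1, k)), targets, rho,
                     with_grad = FALSE)$loss
  }
  gr <- function(p) {
    as.numeric(torque_loss_grad(array(p, c(2, nt - 1, k)), targets, rho)$grad)
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4))
  m_star <- array(0, c(2, nt, k))
  m_star[, 2:nt, ] <- array(opt$par, c(2, nt - 1, k))
  replay <- arm_simulate(m_star, targets$dt, params)
  rms <- sqrt(mean((replay$hand - targets$hand)^2))
  targets$m_star <- m_star
  targets$inversion <- list(loss = opt$value, replay_rms_m = rms,
                            convergence = opt$convergence)
  targets
}
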
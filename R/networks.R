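## Rectified-linear rate networks: construction, inhibitory stabilization,
## and forward simulation.

#' Rectified-linear gain function
#'
#' @param x numeric vector/matrix of internal activations.
#' @return elementwise \code{max(x, 0)} (momentary firing rates).
#' @export
relu <- function(x) pmax(x, 0)

new_network <- function(W, n_exc, n_inh, tau, x_sp, class,
                        seed = NA_integer_, extra = list()) {
  N <- nrow(W)
  stopifnot(ncol(W) == N, n_exc + n_inh == N, length(x_sp) == N)
  h_bar <- x_sp - W %*% relu(x_sp)
  obj <- c(list(
    W = W, n_exc = n_exc, n_inh = n_inh, N = N, tau = tau,
    x_sp = as.numeric(x_sp), h_bar = as.numeric(h_bar),
    sign_labels = rep(c("E", "I"), c(n_exc, n_inh)),
    class = class, seed = seed
  ), extra)
  structure(obj, class = "prepctrl_network")
}

#' @export
print.prepctrl_network <- function(x, ...) {
  cat(sprintf("<prepctrl_network: %s, N=%d (E=%d, I=%d), tau=%g ms, abscissa(W)=%.3f>\n",
              x$class, x$N, x$n_exc, x$n_inh, x$tau, spectral_abscissa(x$W)))
  invisible(x)
}

## Spontaneous activations: i.i.d. Normal(mean 20, sd 3), entries <= 0
## resampled (rates must stay positive for the linearization to hold).
draw_x_sp <- function(n, mean = 20, sd = 3) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

## Random Dale-structured seed connectivity: E columns >= 0, I columns <= 0,
## connection density p, I column magnitudes scaled for E/I balance, whole
## matrix rescaled to the requested spectral abscissa.
random_dale_matrix <- function(n_exc, n_inh, p = 0.1, abscissa = 1.2) {
  N <- n_exc + n_inh
  mask <- matrix(stats::runif(N * N) < p, N, N)
  diag(mask) <- FALSE
  W <- matrix(abs(stats::rnorm(N * N)), N, N) * mask
  ## balance: total I weight per row matches total E weight in expectation
  W[, n_exc + seq_len(n_inh)] <- -W[, n_exc + seq_len(n_inh)] * (n_exc / n_inh)
  a <- spectral_abscissa(W)
  W * (abscissa / a)
}

## Smoothed spectral abscissa (Vanbiervliet et al. style): the unique s >
## alpha(W) at which tr Qc(s) = target, where Qc solves the shifted
## controllability Lyapunov equation (W - sI) Qc + Qc (W - sI)^T + 2I = 0.
## Returns s, Qc and the dual Po for the gradient  d s / d W = Po Qc / tr(Po Qc).
smoothed_abscissa <- function(W, fac = NULL, target_trace = NULL, s0 = NULL) {
  N <- nrow(W)
  if (is.null(fac)) fac <- eigen_factor(W)
  if (is.null(target_trace)) target_trace <- 5 * N  # gap ~ 0.1 above alpha(W)
  lam <- fac$values
  alpha <- max(Re(lam))
  ## W^T = t(Vi) Lambda t(V); the controllability equation
  ## (W-sI) Qc + Qc (W-sI)^T + 2I = 0 is the observability equation for W^T.
  facT <- list(values = lam, V = t(fac$Vi), Vi = t(fac$V))
  ## O(N^2)-per-shift trace: Qc = t(V) Xt(s) V with Xt = -Ct/den(s),
  ## Ct = 2 Vi t(Vi), and tr Qc = sum(t(V %*% t(V)) * Xt).
  Ct <- 2 * (fac$Vi %*% t(fac$Vi))
  G <- t(fac$V) %*% fac$V  # symmetric under plain transpose
  trQ <- function(s) {
    den <- outer(lam - s, lam - s, `+`)
    Re(sum(G * (-Ct / den)))
  }
  ## bracket then bisect the monotonically decreasing tr Qc(s)
  lo <- alpha + 1e-4
  hi <- if (is.null(s0) || s0 <= lo + 1e-6) alpha + 0.2 else s0
  while (trQ(hi) > target_trace) hi <- alpha + 2 * (hi - alpha)
  while (trQ(lo) < target_trace) lo <- alpha + 0.5 * (lo - alpha)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (trQ(mid) > target_trace) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  s <- (lo + hi) / 2
  Qc <- lyap_solve_shifted(facT, s, 2 * diag(N))
  Po <- lyap_solve_shifted(fac, s, diag(N))  # (W-sI)^T Po + Po (W-sI) + I = 0
  PQ <- Po %*% Qc
  grad <- PQ / sum(diag(PQ))
  list(s = s, grad = grad, alpha = alpha)
}

#' Build an inhibition-stabilized network (ISN)
#'
#' Starts from a random Dale-structured connectivity scaled to spectral
#' abscissa 1.2 and iteratively updates the inhibitory columns only, by
#' gradient descent on the smoothed spectral abscissa, stopping as soon as the
#' spectral abscissa of \code{W} drops below \code{abscissa_stop}.
#'
#' @param n_exc,n_inh numbers of excitatory and inhibitory units (160, 40).
#' @param seed RNG seed.
#' @param abscissa_stop early-stopping threshold on the spectral abscissa
#'   (default 0.8).
#' @param tau membrane time constant, ms.
#' @param p connection density of the seed matrix.
#' @param max_iter maximum stabilization iterations.
#' @param lr initial gradient step size.
#' @return a \code{prepctrl_network} of class tag \code{"isn"}.
#' @export
build_isn <- function(n_exc = 160, n_inh = 40, seed = 0, abscissa_stop = 0.8,
                      tau = 150, p = 0.1, max_iter = 600, lr = 3) {
  set.seed(seed)
  N <- n_exc + n_inh
  W <- random_dale_matrix(n_exc, n_inh, p = p, abscissa = 1.2)
  icol <- n_exc + seq_len(n_inh)
  sa <- smoothed_abscissa(W)
  step <- lr
  iter <- 0
  while (sa$alpha >= abscissa_stop) {
    iter <- iter + 1
    if (iter > max_iter) {
      stop(sprintf(paste0("build_isn: stabilization did not reach abscissa %g",
                          " in %d iterations (current %.3f, smoothed %.3f)"),
                   abscissa_stop, max_iter, sa$alpha, sa$s))
    }
    Wnew <- W
    Wnew[, icol] <- pmin(W[, icol] - step * sa$grad[, icol], 0)
    sa_new <- smoothed_abscissa(Wnew, s0 = sa$s)
    if (sa_new$s < sa$s) {
      W <- Wnew
      sa <- sa_new
      step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-8) stop("build_isn: line search stalled")
    }
  }
  x_sp <- draw_x_sp(N)
  new_network(W, n_exc, n_inh, tau, x_sp, "isn", seed,
              extra = list(abscissa_stop = abscissa_stop,
                           stabilization_iters = iter))
}

#' Build a chaotic random network
#'
#' Synaptic weights drawn i.i.d. from a normal distribution with mean
#' \code{-25/N} and variance \code{1.8^2/N}, which places the threshold-linear
#' rate dynamics in the chaotic regime.
#'
#' @param n number of units (200).
#' @param seed RNG seed.
#' @param tau membrane time constant, ms.
#' @param var_scale numerator of the weight variance \code{var_scale/N}
#'   (default \code{1.8^2}).
#' @return a \code{prepctrl_network} of class tag \code{"chaotic"}.
#' @export
build_chaotic <- function(n = 200, seed = 0, tau = 150, var_scale = 1.8^2) {
  set.seed(seed)
  W <- matrix(stats::rnorm(n * n, mean = -25 / n, sd = sqrt(var_scale / n)), n, n)
  x_sp <- draw_x_sp(n)
  new_network(W, n, 0, tau, x_sp, "chaotic", seed)
}

#' Build a low-rank-perturbed random network
#'
#' \eqn{W = W_{base} + u v^T} with \code{Wbase} fixed random
#' (\eqn{N(0, 0.9^2/N)} entries) and \eqn{u, v \in R^{N \times rank}} free
#' parameters (initialized small; trained by \code{\link{calibrate_trained}}).
#'
#' @param n number of units.
#' @param rank rank of the trainable perturbation (5).
#' @param seed RNG seed.
#' @param tau membrane time constant, ms.
#' @return a \code{prepctrl_network} of class tag \code{"lowrank"} carrying
#'   \code{W_base}, \code{u}, \code{v}.
#' @export
build_low_rank <- function(n = 200, rank = 5, seed = 0, tau = 150) {
  set.seed(seed)
  W_base <- matrix(stats::rnorm(n * n, 0, 0.9 / sqrt(n)), n, n)
  u <- matrix(stats::rnorm(n * rank, 0, 1e-3), n, rank)
  v <- matrix(stats::rnorm(n * rank, 0, 1e-3), n, rank)
  W <- W_base + u %*% t(v)
  x_sp <- draw_x_sp(n)
  new_network(W, n, 0, tau, x_sp, "lowrank", seed,
              extra = list(W_base = W_base, u = u, v = v, rank = rank))
}

#' Condition-independent movement-epoch input
#'
#' Spatially uniform alpha-shaped input bump
#' \eqn{h(t) = A [\exp(-(t - t_{move})/\tau_{decay}) -
#' \exp(-(t - t_{move})/\tau_{rise})]} for \eqn{t > t_{move}}, zero before.
#' The amplitude \code{A} is solved analytically so the peak equals
#' \code{peak}: the bump peaks at \eqn{t_{move} + \frac{\tau_r \tau_d}
#' {\tau_d - \tau_r} \log(\tau_d/\tau_r)}.
#'
#' @param t_grid times (ms) at which to evaluate.
#' @param t_move movement onset time (ms).
#' @param tau_rise,tau_decay rise and decay constants, ms (50, 500); must
#'   satisfy \code{tau_rise < tau_decay}.
#' @param peak desired maximum of the bump (5).
#' @return numeric vector \code{h(t_grid)} (per-neuron amplitude; the input is
#'   uniform across neurons).
#' @export
transient_input <- function(t_grid, t_move = 0, tau_rise = 50,
                            tau_decay = 500, peak = 5) {
  if (tau_rise >= tau_decay) {
    stop("transient_input: tau_rise must be < tau_decay")
  }
  t_pk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  A <- peak / (exp(-t_pk / tau_decay) - exp(-t_pk / tau_rise))
  s <- t_grid - t_move
  h <- ifelse(s > 0, A * (exp(-s / tau_decay) - exp(-s / tau_rise)), 0)
  attr(h, "amplitude") <- A
  attr(h, "peak_time") <- t_move + t_pk
  h
}

#' Simulate network dynamics (forward Euler)
#'
#' Integrates \eqn{\tau \dot x = -x + W \phi(x) + \bar h + h(t) + u(t)} from
#' \code{x0} with time step \code{dt}.
#'
#' @param model a \code{prepctrl_network}.
#' @param T_ms duration, ms.
#' @param x0 initial activation vector, or matrix (N x n_cond) to integrate
#'   several conditions in parallel (default: spontaneous state).
#' @param u_fn \code{NULL} (no control) or \code{function(t, x)} returning the
#'   control input (vector or N x n_cond matrix).
#' @param h_fn \code{NULL} or \code{function(t)} returning the scalar
#'   condition-independent input applied uniformly to all neurons.
#' @param dt Euler step, ms (must not exceed tau/10).
#' @param linear if \code{TRUE} integrate the linearized dynamics
#'   (\eqn{\phi} replaced by identity).
#' @param diverge_norm declare instability when any state norm exceeds this.
#' @return object of class \code{prepctrl_trajectory}: list with \code{times}
#'   (ms), \code{x} (N x T x n_cond array), \code{rates} = \eqn{\phi(x)}.
#' @export
simulate <- function(model, T_ms, x0 = NULL, u_fn = NULL, h_fn = NULL,
                     dt = 1, linear = FALSE, diverge_norm = 1e6) {
  stopifnot(dt <= model$tau / 10)
  N <- model$N
  if (is.null(x0)) x0 <- model$x_sp
  X <- if (is.matrix(x0)) x0 else matrix(x0, N, 1)
  n_cond <- ncol(X)
  nt <- floor(T_ms / dt) + 1
  times <- (seq_len(nt) - 1) * dt
  out <- array(NA_real_, c(N, nt, n_cond))
  W <- model$W; tau <- model$tau; h_bar <- model$h_bar
  phi <- if (linear) identity else relu
  for (i in seq_len(nt)) {
    out[, i, ] <- X
    if (i == nt) break
    t_now <- times[i]
    drive <- W %*% phi(X) + h_bar - X
    if (!is.null(h_fn)) drive <- drive + h_fn(t_now)
    if (!is.null(u_fn)) drive <- drive + u_fn(t_now, X)
    X <- X + (dt / tau) * drive
    if (max(colSums(X^2)) > diverge_norm^2) {
      stop(sprintf("simulate: state norm exceeded %g at t=%g ms (unstable?)",
                   diverge_norm, t_now))
    }
  }
  structure(list(times = times, x = out, rates = relu(out), dt = dt,
                 linear = linear),
            class = "prepctrl_trajectory")
}

#' @export
print.prepctrl_trajectory <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<prepctrl_trajectory: %d neurons, %d steps (dt=%g ms), %d condition(s)>\n",
              d[1], d[2], x$dt, d[3]))
  invisible(x)
}
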
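## Small calibrated system shared across control tests (built once).
small_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_isn(32, 8, seed = 3, p = 0.5)
      set.seed(30)
      N <- net$N
      ## modest synthetic task: random readout + initial states with the
      ## structural nullspace constraints of a calibrated task
      Xs <- net$x_sp + matrix(rnorm(N * 4, 0, 3), N, 4)
      S <- cbind(net$x_sp, Xs)
      Pn <- diag(N) - S %*% solve(crossprod(S), t(S))
      C <- matrix(rnorm(2 * N, 0, 0.2), 2, N) %*% Pn
      C[, 33:40] <- 0
      cache <<- list(net = net, C = C, Xs = Xs)
    }
    cache
  }
})

test_that("observability Gramian solves the Lyapunov equation with Tr(Q)=N", {
  s <- small_setup()
  A <- s$net$W - diag(s$net$N)
  Q <- observability_gramian(A, s$C, normalize = FALSE)
  expect_lt(norm(t(A) %*% Q + Q %*% A + crossprod(s$C), "F") /
              norm(crossprod(s$C), "F"), 1e-8)
  Qn <- observability_gramian(A, s$C)
  expect_equal(sum(diag(Qn)), s$net$N, tolerance = 1e-10)
  ## C = 0: zero Gramian, normalization skipped
  expect_equal(observability_gramian(A, matrix(0, 2, s$net$N)),
               matrix(0, s$net$N, s$net$N), tolerance = 1e-12)
  ## A = -I: Q = C'C / 2 before normalization
  expect_equal(observability_gramian(-diag(s$net$N), s$C, normalize = FALSE),
               crossprod(s$C) / 2, tolerance = 1e-10)
  ## unstable A: identity fallback only when requested
  expect_error(observability_gramian(diag(2), matrix(1, 1, 2)), "Hurwitz")
  expect_equal(observability_gramian(diag(2), matrix(1, 1, 2),
                                     allow_unstable = TRUE), diag(2))
})

test_that("prospective error equals simulated future torque error in the linear regime", {
  s <- small_setup()
  net <- s$net; N <- net$N
  A <- net$W - diag(N)
  Q <- observability_gramian(A, s$C, normalize = FALSE)
  x_star <- s$Xs[, 1]
  set.seed(31)
  for (r in 1:4) {
    dx <- rnorm(N); dx <- dx / sqrt(sum(dx^2)) * 2
    ## simulated (linear) torque-error integral, d t' / tau
    dt <- 1
    ts <- seq(0, 4000, dt)
    err <- 0
    for (t in ts) {
      d <- expm_eig(A * t / net$tau) %*% dx
      err <- err + sum((s$C %*% d)^2) * dt / net$tau
    }
    expect_equal(drop(prospective_error(x_star + dx, x_star, Q)), err,
                 tolerance = 0.05 * err)
  }
  ## Rayleigh-quotient extremes
  e <- eigen(Q, symmetric = TRUE)
  expect_equal(prospective_error(x_star + e$vectors[, 1], x_star, Q),
               e$values[1], tolerance = 1e-8)
  expect_equal(prospective_error(x_star, x_star, Q), 0)
})

test_that("LQR gain is optimal, stabilizing and condition-independent", {
  s <- small_setup()
  A <- s$net$W - diag(s$net$N)
  Q <- observability_gramian(A, s$C)
  law <- lqr_gain(A, Q, lambda = 0.1)
  expect_lt(spectral_abscissa(law$A_cl), 0)
  expect_equal(law$K, -law$P / 0.1)
  ## Q = 0 -> P = 0, K = 0
  law0 <- lqr_gain(A, matrix(0, nrow(A), nrow(A)))
  expect_equal(law0$K, matrix(0, nrow(A), nrow(A)), tolerance = 1e-9)
  ## cost identity: total = prospective + lambda * energy
  set.seed(32)
  dx0 <- matrix(rnorm(2 * s$net$N, 0, 2), s$net$N, 2)
  cr <- cost_report(law, dx0)
  expect_equal(cr$total, cr$prospective + 0.1 * cr$energy, tolerance = 1e-8)
  expect_true(all(cr$energy >= 0) && all(cr$prospective >= -1e-10))
})

test_that("steady input establishes the target fixed point; naive feedforward converges to it", {
  s <- small_setup()
  net <- s$net
  x_star <- s$Xs[, 2]
  u <- steady_input(x_star, net)
  tr <- simulate(net, 300, x0 = x_star, u_fn = function(t, X) u)
  expect_lt(max(abs(tr$x[, dim(tr$x)[2], 1] - x_star)), 1e-8)
  ## from spontaneous activity, the state decays toward x_star
  tr2 <- simulate(net, 3000, u_fn = function(t, X) matrix(u, net$N, 1))
  d0 <- sqrt(sum((net$x_sp - x_star)^2))
  dT <- sqrt(sum((tr2$x[, dim(tr2$x)[2], 1] - x_star)^2))
  expect_lt(dT, 0.05 * d0)
})

test_that("chaotic networks defeat naive feedforward preparation", {
  net <- build_chaotic(80, seed = 4)
  set.seed(33)
  x_star <- net$x_sp + rnorm(net$N, 0, 3)
  u <- steady_input(x_star, net)
  tr <- simulate(net, 4000, u_fn = function(t, X) matrix(u, net$N, 1),
                 diverge_norm = 1e7)
  dT <- sqrt(sum((tr$x[, dim(tr$x)[2], 1] - x_star)^2))
  d0 <- sqrt(sum((net$x_sp - x_star)^2))
  expect_gt(dT, 0.5 * d0)   # no convergence to the would-be fixed point
})

test_that("large-lambda LQR approaches the naive feedforward solution", {
  s <- small_setup()
  A <- s$net$W - diag(s$net$N)
  Q <- observability_gramian(A, s$C)
  law_inf <- lqr_gain(A, Q, lambda = 1e6)
  expect_lt(norm(law_inf$K, "F"), 1e-2)
})

test_that("energy/prospective trade-off over lambda is monotone", {
  s <- small_setup()
  A <- s$net$W - diag(s$net$N)
  Q <- observability_gramian(A, s$C)
  set.seed(34)
  dx0 <- rnorm(s$net$N, 0, 2)
  lambdas <- c(0.01, 0.1, 1, 10)
  en <- pr <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    law <- lqr_gain(A, Q, lambda = lambdas[i])
    cr <- cost_report(law, dx0)
    en[i] <- cr$energy; pr[i] <- cr$prospective
  }
  expect_true(all(diff(en) < 0))   # larger penalty -> less energy spent
  expect_true(all(diff(pr) > 0))   # ... at the price of prospective cost
})

test_that("nullspace-weighted Gramian blends to the stated limits", {
  s <- small_setup()
  A <- s$net$W - diag(s$net$N)
  Q <- observability_gramian(A, s$C)
  N <- nrow(Q)
  expect_equal(nullspace_weighted_gramian(Q, s$C, 1), Q)
  Q0 <- nullspace_weighted_gramian(Q, s$C, 0)
  CtC <- crossprod(s$C)
  expect_equal(Q0, N * CtC / sum(diag(CtC)), tolerance = 1e-12)
  expect_equal(sum(diag(nullspace_weighted_gramian(Q, s$C, 0.2))), N,
               tolerance = 1e-8)
})

test_that("preparing under the nullspace-weighted Gramian suppresses output torques", {
  task <- tiny_task()
  A <- task$model$W - diag(task$model$N)
  Q <- observability_gramian(A, task$C)
  Qt <- nullspace_weighted_gramian(Q, task$C, eta = 0.2)
  prep_torque_power <- function(law) {
    res <- prepare_lqr(task, law, prep_ms = 300, move_ms = 10)
    k <- dim(res$prep$rates)[3]
    total <- 0
    for (j in seq_len(k)) {
      total <- total + sum((task$C %*% res$prep$rates[, , j])^2)
    }
    total
  }
  p_q <- prep_torque_power(lqr_gain(A, Q, lambda = 0.1))
  p_qt <- prep_torque_power(lqr_gain(A, Qt, lambda = 0.1))
  expect_lt(p_qt, p_q)
})

test_that("naive feedforward step response contains the impulse-response timescales", {
  ## in a linear network the step response to u* is
  ## (I - e^{tA/tau})(x* - xsp): same eigen-timescales as the impulse
  ## response e^{tA/tau} x*.
  s <- small_setup()
  net <- s$net
  A <- net$W - diag(net$N)
  x_star <- s$Xs[, 3]
  u <- steady_input(x_star, net)
  tr <- simulate(net, 1000, u_fn = function(t, X) matrix(u, net$N, 1),
                 linear = TRUE)
  idx <- seq(1, 1001, 10)
  pred <- sapply(tr$times[idx], function(t) {
    d <- (diag(net$N) - expm_eig(A * t / net$tau)) %*% (x_star - net$x_sp)
    net$x_sp + d
  })
  expect_lt(max(abs(tr$x[, idx, 1] - pred)), 0.05)
})
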
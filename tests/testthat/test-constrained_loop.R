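## Small systems exercise the structured-gain machinery; the full
## thalamo-cortical circuit is built in the acceptance suite.

make_small_problem <- function(n = 6, n_read = 4, seed = 40) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n) * 0.3 - diag(n)
  C <- matrix(rnorm(2 * n), 2, n)
  Q <- lyap_solve(A, crossprod(C))
  Q <- Q * (n / sum(diag(Q)))
  Gamma <- cbind(diag(n_read), matrix(0, n_read, n - n_read))
  structured_gain_problem(A, Q, Gamma, lambda = 0.1)
}

test_that("structured-gain gradient matches finite differences", {
  prob <- make_small_problem()
  set.seed(41)
  for (r in 1:3) {
    Z <- matrix(rnorm(6 * 4, 0, 0.5), 6, 4)
    out <- sgp_cost_grad(prob, Z)
    if (!is.finite(out$J)) next
    eps <- 1e-6
    idx <- sample(length(Z), 8)
    for (q in idx) {
      Zp <- Z; Zp[q] <- Zp[q] + eps
      Jp <- sgp_cost_grad(prob, Zp, with_grad = FALSE)$J
      expect_equal(out$grad[q], (Jp - out$J) / eps, tolerance = 1e-3)
    }
  }
})

test_that("full-state selector recovers the unconstrained LQR solution", {
  set.seed(42)
  n <- 6
  A <- matrix(rnorm(n * n), n, n) * 0.3 - diag(n)
  C <- matrix(rnorm(2 * n), 2, n)
  Q <- lyap_solve(A, crossprod(C)); Q <- Q * (n / sum(diag(Q)))
  prob <- structured_gain_problem(A, Q, diag(n), lambda = 0.1)
  res <- optimize_structured_gain(prob, maxit = 300, factr = 1e5)
  expect_equal(res$J, res$J_lqr, tolerance = 1e-5 * res$J_lqr)
  expect_lt(norm(res$K - res$K_lqr, "F") / norm(res$K_lqr, "F"), 1e-2)
})

test_that("optimality ordering: unconstrained <= partial-state <= lagged loop", {
  net <- build_isn(24, 6, seed = 7, p = 0.5)
  N <- net$N; NE <- net$n_exc
  A <- net$W - diag(N)
  set.seed(43)
  C <- matrix(rnorm(2 * N, 0, 0.2), 2, N); C[, (NE + 1):N] <- 0
  Q <- observability_gramian(A, C)
  lam <- 0.1
  ## E-only instantaneous feedback
  probE <- structured_gain_problem(A, Q, cbind(diag(NE),
                                               matrix(0, NE, N - NE)), lam)
  resE <- optimize_structured_gain(probE, maxit = 200)
  expect_gte(resE$J, resE$J_lqr - 1e-6 * resE$J_lqr)
  expect_lt(resE$J, 3 * resE$J_lqr)   # within a small factor
  ## lagged thalamo-cortical loop: more constrained still
  prob2 <- build_augmented_system(net, Q, lambda = lam, seed = 1)
  res2 <- optimize_structured_gain(prob2, maxit = 200)
  ## costs on the same (A, Q, lambda): augmented LQR bound is below both
  expect_gte(res2$J, res2$J_lqr - 1e-6 * res2$J_lqr)
  expect_gte(res2$J, resE$J - 0.05 * resE$J)
})

test_that("Dale factorization is sign-exact and rebalancing preserves the product", {
  set.seed(44)
  Z <- matrix(rnorm(20 * 12), 20, 12)
  fact <- dale_decompose(Z, m_exc = 30, m_inh = 30, seed = 1, maxit = 800)
  expect_true(all(fact$Kzy >= 0))
  expect_true(all(fact$Kxz[, 1:30] >= 0))
  expect_true(all(fact$Kxz[, 31:60] <= 0))
  expect_lt(fact$rel_err, 0.05)
  ## rebalancing leaves the product unchanged
  Kyx <- matrix(runif(12 * 20), 12, 20)
  K0 <- fact$Kxz %*% fact$Kzy %*% Kyx
  n1 <- norm(fact$Kxz, "F"); n2 <- norm(fact$Kzy, "F"); n3 <- norm(Kyx, "F")
  g <- (n1 * n2 * n3)^(1 / 3)
  K1 <- (fact$Kxz * g / n1) %*% (fact$Kzy * g / n2) %*% (Kyx * g / n3)
  expect_equal(K1, K0, tolerance = 1e-10)
})

test_that("augmented linear system reproduces the three-population simulation", {
  net <- build_isn(16, 4, seed = 8, p = 0.5)
  N <- net$N; NE <- net$n_exc
  set.seed(45)
  C <- matrix(rnorm(2 * N, 0, 0.2), 2, N); C[, (NE + 1):N] <- 0
  Q <- observability_gramian(net$W - diag(N), C)
  prob <- build_augmented_system(net, Q, lambda = 0.01, seed = 2)
  Z <- matrix(rnorm(N * NE, 0, 0.05), N, NE)
  Acl <- prob$A + prob$B %*% Z %*% prob$Gamma
  ## simulate the augmented linear system by Euler
  dt <- 0.5; nt <- 400
  s <- c(rnorm(N, 0, 1), rep(0, 2 * NE))
  S <- matrix(NA_real_, length(s), nt)
  for (i in 1:nt) { S[, i] <- s; s <- s + (dt / net$tau) * (Acl %*% s) }
  ## against the explicit x/y/z recursion of the loop equations
  x <- S[1:N, 1]; y <- rep(0, NE); z <- rep(0, NE)
  X2 <- matrix(NA_real_, N, nt)
  for (i in 1:nt) {
    X2[, i] <- x
    xn <- x + (dt / net$tau) * (-x + net$W %*% x + Z %*% z)
    yn <- y + (dt / 10) * (-y + prob$R %*% x[1:NE])
    zn <- z + (dt / 10) * (-z + y)
    x <- xn; y <- yn; z <- zn
  }
  expect_lt(max(abs(S[1:N, ] - X2)), 1e-8)
})

test_that("vanishing loop lags recover instantaneous feedback behavior", {
  net <- build_isn(12, 4, seed = 9, p = 0.6)
  N <- net$N; NE <- net$n_exc
  set.seed(46)
  C <- matrix(rnorm(2 * N, 0, 0.3), 2, N); C[, (NE + 1):N] <- 0
  Q <- observability_gramian(net$W - diag(N), C)
  ## an arbitrary E-only gain applied (a) instantaneously, (b) via a fast loop
  Zk <- matrix(rnorm(N * NE, 0, 0.1), N, NE)
  Gam <- cbind(diag(NE), matrix(0, NE, N - NE))
  K <- Zk %*% Gam
  A <- net$W - diag(N)
  dt <- 0.02; nt <- 2000
  x0 <- rnorm(N)
  run_inst <- function() {
    x <- x0; out <- matrix(NA_real_, N, nt)
    for (i in 1:nt) { out[, i] <- x; x <- x + (dt / net$tau) * ((A + K) %*% x) }
    out
  }
  run_loop <- function(tl) {
    x <- x0; y <- x0[1:NE]; z <- x0[1:NE]  # start loop states at equilibrium-ish
    y <- x[1:NE]; z <- x[1:NE]
    out <- matrix(NA_real_, N, nt)
    for (i in 1:nt) {
      out[, i] <- x
      xn <- x + (dt / net$tau) * (A %*% x + Zk %*% z)
      yn <- y + (dt / tl) * (-y + x[1:NE])
      zn <- z + (dt / tl) * (-z + y)
      x <- xn; y <- yn; z <- zn
    }
    out
  }
  ref <- run_inst()
  err_slow <- max(abs(run_loop(5) - ref))
  err_fast <- max(abs(run_loop(0.5) - ref))
  expect_lt(err_fast, err_slow / 3)
})
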
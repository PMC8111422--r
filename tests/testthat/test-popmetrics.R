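test_that("participation ratio follows the closed form", {
  expect_equal(participation_ratio(c(1, 1, 1)), 3)
  expect_equal(participation_ratio(c(1, 0, 0)), 1)
  expect_equal(participation_ratio(c(4, 2, 1, 1)), 64 / 22)
  expect_error(participation_ratio(c(0, 0)), "zero")
})

test_that("nonnormality index separates normal, nilpotent and generic matrices", {
  S <- crossprod(matrix(rnorm(25), 5, 5))
  expect_equal(nonnormality_index(S), 0, tolerance = 1e-10)
  expect_equal(nonnormality_index(matrix(c(0, 0, 1, 0), 2, 2)), 1)
  ## generic: matches a Schur-form oracle (Frobenius energy outside the
  ## diagonal blocks of the real Schur form, block eigenvalues computed
  ## per 1x1 / 2x2 block)
  set.seed(21)
  W <- matrix(rnorm(64), 8, 8)
  sch <- Matrix::Schur(W)
  Tm <- as.matrix(sch$T)
  lam_energy <- 0
  i <- 1
  while (i <= 8) {
    if (i < 8 && abs(Tm[i + 1, i]) > 1e-10) {
      lam_energy <- lam_energy +
        sum(Mod(eigen(Tm[i:(i + 1), i:(i + 1)], only.values = TRUE)$values)^2)
      i <- i + 2
    } else {
      lam_energy <- lam_energy + Tm[i, i]^2
      i <- i + 1
    }
  }
  expect_equal(nonnormality_index(W), (sum(Tm^2) - lam_energy) / sum(Tm^2),
               tolerance = 1e-8)
  expect_error(nonnormality_index(matrix(0, 3, 3)), "zero")
})

test_that("H2 norm closed forms and scaling", {
  expect_equal(h2_norm(-diag(200)), 100)
  expect_equal(h2_norm(-2 * diag(200)), 50)
  ## quadrature oracle on a small system
  set.seed(22)
  A <- matrix(rnorm(64), 8, 8) * 0.2 - diag(8)
  dt <- 0.002
  acc <- 0
  for (t in seq(0, 60, dt)) {
    E <- expm_eig(A * t)
    acc <- acc + sum(E^2) * dt
  }
  expect_equal(h2_norm(A), acc, tolerance = 5e-3)
  expect_error(h2_norm(diag(3)), "stable")
})

test_that("subspace potency is the mean Rayleigh quotient", {
  set.seed(23)
  Q <- crossprod(matrix(rnorm(100), 10, 10))
  e <- eigen(Q, symmetric = TRUE)
  expect_equal(subspace_potency(Q, e$vectors[, 1]), e$values[1],
               tolerance = 1e-10)
  expect_equal(subspace_potency(Q, e$vectors), mean(e$values),
               tolerance = 1e-10)
  expect_error(subspace_potency(Q, matrix(1, 10, 2)), "orthonormal")
})

test_that("alignment index: identical, orthogonal and random cases", {
  set.seed(24)
  N <- 40; nt <- 30; k <- 6
  d1 <- array(rnorm(N * nt * k), c(N, nt, k))
  ep <- epoch_data(d1, "prep")
  expect_equal(alignment_index(ep, epoch_data(d1, "move")), 1,
               tolerance = 1e-10)
  ## orthogonal coordinate blocks with matching spectra -> 0
  d2 <- array(0, c(N, nt, k)); d3 <- array(0, c(N, nt, k))
  L <- array(rnorm(5 * nt * k), c(5, nt, k))
  d2[1:5, , ] <- L; d3[6:10, , ] <- L
  expect_equal(alignment_index(epoch_data(d2), epoch_data(d3)), 0,
               tolerance = 1e-10)
  ## random-overlap chance level: for independent isotropic epochs, the raw
  ## fraction of prep variance captured by K random move-PCs is K/N in
  ## expectation (the normalization to top-K prep eigenvalues approaches 1
  ## for isotropic data, so the unnormalized fraction is the quantity with
  ## an analytic chance level)
  nt2 <- 200; k2 <- 8; Ksub <- 5
  fracs <- replicate(8, {
    a <- array(rnorm(N * nt2 * k2), c(N, nt2, k2))
    b <- array(rnorm(N * nt2 * k2), c(N, nt2, k2))
    Cp <- epoch_cov(epoch_data(a))
    D <- eigen(epoch_cov(epoch_data(b)), symmetric = TRUE)$vectors[, 1:Ksub]
    sum(colSums(D * (Cp %*% D))) / sum(diag(Cp))
  })
  expect_lt(abs(mean(fracs) - Ksub / N), 0.04)
})

test_that("alignment index is invariant to a global rotation of both epochs", {
  set.seed(25)
  N <- 30
  fx <- generate_psths(psth_spec(n_neurons = N, rank_prep = 3, rank_move = 3,
                                 angle_deg = 45, n_time = 40), seed = 1)
  a0 <- alignment_index(fx$prep, fx$move)
  R <- qr.Q(qr(matrix(rnorm(N * N), N, N)))
  rot <- function(ep) {
    d <- ep$rates
    for (j in seq_len(dim(d)[3])) d[, , j] <- R %*% d[, , j]
    epoch_data(d, ep$epoch)
  }
  expect_equal(alignment_index(rot(fx$prep), rot(fx$move)), a0,
               tolerance = 1e-8)
})

test_that("jPCA recovers a planted rotational generator", {
  set.seed(26)
  N <- 20; nt <- 100; k <- 4
  th <- 0.07
  S0 <- matrix(0, 6, 6)
  S0[1, 2] <- th; S0[2, 1] <- -th; S0[3, 4] <- th / 3; S0[4, 3] <- -th / 3
  B <- qr.Q(qr(matrix(rnorm(N * 6), N, 6)))
  data <- array(0, c(N, nt, k))
  for (j in 1:k) {
    x <- rnorm(6, 0, 3)
    for (i in 1:nt) { data[, i, j] <- B %*% x; x <- x + S0 %*% x }
  }
  fit <- jpca(data, dt = 1, n_pc = 6)
  expect_equal(fit$S, -t(fit$S), tolerance = 1e-12)  # exact skew symmetry
  expect_gt(fit$r2, 0.95)
  ## top rotation frequency recovered
  f_true <- th
  f_fit <- max(abs(Im(eigen(fit$S, only.values = TRUE)$values)))
  expect_equal(f_fit, f_true, tolerance = 0.01)
  ## static (time-constant) data -> S = 0
  static <- array(0, c(N, nt, k))
  for (j in 1:k) static[, , j] <- rnorm(N, 0, 2)
  fit0 <- jpca(static, n_pc = 3)
  expect_lt(max(abs(fit0$S)), 1e-10)
})

test_that("canonical correlations: rotation invariance and chance level", {
  set.seed(27)
  N <- 25; nt <- 60; k <- 4
  A <- array(rnorm(N * nt * k), c(N, nt, k))
  R <- qr.Q(qr(matrix(rnorm(N * N), N, N)))
  B <- A
  for (j in 1:k) B[, , j] <- R %*% A[, , j]
  cors <- cca_compare(A, B, var_kept = 0.5)
  expect_true(all(cors > 0.999))
  expect_true(all(diff(cors) <= 1e-12))
  ## independent data: compare against a permutation null
  Bi <- array(rnorm(N * nt * k), c(N, nt, k))
  c_ind <- cca_compare(A, Bi, var_kept = 0.3)
  null_top <- replicate(20, {
    idx <- sample(nt * k)
    Bp <- array(matrix(Bi, N)[, idx], c(N, nt, k))
    cca_compare(A, Bp, var_kept = 0.3)[1]
  })
  expect_lt(c_ind[1], max(null_top) + 0.1)
})
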
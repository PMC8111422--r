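## Reduced-scale versions of the in-silico experiments; the full-scale runs
## live in the acceptance suite.

test_that("perturbation classes are ordered potent > readout-null > dynamic-null", {
  task <- tiny_task()
  tax <- perturbation_taxonomy(task, cond = 1, move_ms = 500)
  ## torque consequences: potent dominates, dynamic-null negligible
  tq <- vapply(tax[c("potent", "readout_null", "dynamic_null")],
               function(x) sqrt(mean(x$torque_rms^2)), 0)
  expect_gt(tq["potent"], 5 * tq["readout_null"])
  expect_gt(tq["potent"], 5 * tq["dynamic_null"])
  ## readout-null perturbations still move the network state appreciably,
  ## dynamic-null ones are rejected by the dynamics (all classes share the
  ## same initial norm, so compare propagated activity after the onset)
  act <- vapply(tax[c("potent", "readout_null", "dynamic_null")],
                function(x) mean(x$activity_rms[-(1:100)]), 0)
  ## at this small scale the contrast is modest; the full-scale separation
  ## is asserted in the acceptance suite
  expect_gt(act["readout_null"], 1.3 * act["dynamic_null"])
  ## Gramian potency ranks match
  expect_gt(tax$potent$potency, tax$readout_null$potency)
})

test_that("gated loop: thalamus silent while the gate is closed, prepares while open", {
  circ <- tiny_loop()
  tr <- simulate_gated_loop(circ, prep_ms = 400, move_ms = 200, pre_ms = 60)
  ipre <- which(tr$times < 0)
  expect_equal(max(abs(tr$y[, ipre, ])), 0)
  expect_lt(max(abs(tr$x[, ipre, 1] - circ$task$model$x_sp)), 1e-6)
  ## preparation reduces the distance to the desired state
  iend <- which.min(abs(tr$times - tr$go_ms))
  d0 <- sqrt(colSums((circ$task$model$x_sp - circ$task$x_star)^2))
  dT <- sqrt(colSums((tr$x[, iend, ] - circ$task$x_star)^2))
  expect_true(all(dT < 0.5 * d0))
  ## after the go cue thalamus is silenced again
  imove <- which(tr$times > tr$go_ms + 2)
  expect_equal(max(abs(tr$y[, imove, ])), 0)
})

test_that("loop preparation beats naive feedforward in prospective error", {
  circ <- tiny_loop()
  task <- circ$task
  model <- task$model
  Q <- circ$Q
  prep_ms <- 300
  tr <- simulate_gated_loop(circ, prep_ms = prep_ms, move_ms = 0, pre_ms = 0)
  iend <- dim(tr$x)[2]
  loop_err <- mean(prospective_error(matrix(tr$x[, iend, ], model$N),
                                     task$x_star, Q))
  u_star <- steady_input(task$x_star, model)
  trn <- simulate(model, prep_ms,
                  x0 = matrix(model$x_sp, model$N, ncol(task$x_star)),
                  u_fn = function(t, X) u_star)
  naive_err <- mean(prospective_error(
    matrix(trn$x[, dim(trn$x)[2], ], model$N), task$x_star, Q))
  expect_lt(loop_err, 0.5 * naive_err)
})

test_that("refit preserves the readout and restores movement accuracy", {
  task <- tiny_task()
  circ <- build_loop_circuit(task, lambda = 0.01, m_exc = 30, m_inh = 30,
                             seed = 2, maxit_gain = 40, maxit_dale = 300)
  C_before <- circ$task$C
  circ2 <- refit_initial_states(circ, maxit = 120)
  expect_identical(circ2$task$C, C_before)       # C held fixed bit-for-bit
  ## the closed-loop gain matrices are untouched by the refit
  expect_identical(circ2$K, circ$K)
  ## movement with the layer-4 decay transient reproduces the targets better
  ## from the refit states than from the original ones
  tr_old <- simulate_gated_loop(circ, prep_ms = 1200)
  tr_new <- simulate_gated_loop(circ2, prep_ms = 1200)
  expect_lt(tr_new$endpoint_err_m, tr_old$endpoint_err_m + 1e-9)
})

test_that("photoinhibition suppresses untargeted cells and resets then recovers the preparatory state", {
  circ <- tiny_loop()
  ph <- run_photoinhibition(circ, n_experiments = 4, seed = 3,
                            prep_ms = 1000, onset = 300, Tph = 300,
                            move_ms = 100)
  ## paradoxical suppression: untargeted I cells and E cells are (weakly)
  ## suppressed on average during the perturbation
  expect_lt(mean(ph$rates$untargeted_i[, 1]), mean(ph$rates$untargeted_i[, 2]))
  expect_lt(mean(ph$rates$e[, 1]), mean(ph$rates$e[, 2]))
  ## subspace geometry: bases orthonormal, RS orthogonal to CS and PS
  dec <- decompose_cs_ps_rs(ph$Xunpert, ph$Xpert[[1]])
  expect_lt(max(abs(crossprod(dec$U_rs, dec$U_cs))), 1e-8)
  expect_lt(max(abs(crossprod(dec$U_rs, dec$U_ps))), 1e-8)
  expect_equal(crossprod(dec$U_cs), diag(ncol(dec$U_cs)), tolerance = 1e-10)
  expect_gt(dec$var_captured, 0.9)
  ## deviations shrink after the perturbation ends along the coding subspace
  ## (the full-scale selective-recovery comparison lives in the acceptance
  ## suite; at this scale only the recovery itself is robust)
  t_pe <- which.min(abs(ph$times - 600))     # perturbation end
  t_end <- which.min(abs(ph$times - 1000))   # end of preparation
  expect_lt(ph$dev[t_end, 1], 0.35 * ph$dev[t_pe, 1])
})

test_that("orthogonality suite returns valid indices for all strategies", {
  ## the naive > LQR ordering is a full-scale claim checked in the
  ## acceptance suite; here we check the machinery end to end
  task <- tiny_task()
  A <- task$model$W - diag(task$model$N)
  Q <- observability_gramian(A, task$C)
  law <- lqr_gain(A, Q, lambda = 0.1)
  orth <- orthogonality_suite(task, law, prep_ms = 500)
  expect_named(orth$alignment, c("lqr", "instant", "naive"))
  expect_true(all(orth$alignment >= 0 & orth$alignment <= 1))
  expect_gt(orth$dim_prep, 1)
  expect_gt(orth$dim_move, 1)
})

test_that("surrogate networks show a higher instant alignment index than the original", {
  task <- tiny_task()
  surr <- make_normal_surrogate(task)
  ## instant strategy: prep activity clamped at the end state; movement from
  ## the respective initial conditions (linear regime for the surrogate)
  window <- 300
  inst_index <- function(C, A, x_star, x_sp, tau) {
    k <- ncol(x_star)
    nt <- window + 1
    prep <- array(rep(x_star, each = 1), c(nrow(x_star), nt, k))
    for (i in seq_len(nt)) prep[, i, ] <- x_star
    move <- array(NA_real_, c(nrow(x_star), nt, k))
    X <- x_star
    for (i in seq_len(nt)) {
      move[, i, ] <- X
      X <- X + (1 / tau) * (A %*% (X - x_sp))
    }
    alignment_index(epoch_data(prep), epoch_data(move))
  }
  A <- task$model$W - diag(task$model$N)
  a_orig <- inst_index(task$C, A, task$x_star, task$model$x_sp,
                       task$model$tau)
  a_surr <- inst_index(surr$C_tilde, surr$A_tilde, surr$x_star_tilde,
                       surr$x_sp, task$model$tau)
  expect_gt(a_surr, a_orig)
})
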
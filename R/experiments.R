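## Scripted in-silico experiments: perturbation taxonomy, photoinhibition of
## the gated loop with coding/persistent/remaining subspace analysis, and the
## preparatory-vs-movement orthogonality comparison.

#' Classify initial-condition perturbations by prospective potency
#'
#' Applies equal-norm perturbations of the movement-specific initial state
#' along three directions: prospectively potent (top eigenvector of the
#' readout Gramian Q), prospectively readout-null (a bottom-Q direction whose
#' propagated activity is nevertheless large, by the full-state Gramian), and
#' prospectively dynamic-null (a bottom-Q direction rejected by the
#' dynamics). Each perturbed movement is simulated and activity, torque and
#' hand errors reported over time.
#'
#' @param task a calibrated \code{prepctrl_task}.
#' @param cond index of the movement condition to perturb.
#' @param norm_frac perturbation norm as a fraction of
#'   \eqn{\|x^* - x_{sp}\|} (0.1).
#' @param move_ms movement duration, ms.
#' @param null_pool number of bottom-Q eigenvectors searched for the
#'   readout-null / dynamic-null extremes.
#' @return list of class \code{prepctrl_taxonomy}: per-class time courses of
#'   activity RMS error, torque RMS error and hand deviation, plus the
#'   directions used and their Q-potencies.
#' @export
perturbation_taxonomy <- function(task, cond = 1, norm_frac = 0.1,
                                  move_ms = 800, null_pool = 100) {
  model <- task$model
  N <- model$N
  null_pool <- min(null_pool, floor(N / 2))
  A <- model$W - diag(N)
  Q <- observability_gramian(A, task$C, allow_unstable = TRUE)
  Wo <- lyap_solve(A, diag(N))            # full-state (activity) Gramian
  eq <- eigen(Q, symmetric = TRUE)
  potent <- eq$vectors[, 1]
  bottom <- eq$vectors[, (N - null_pool + 1):N, drop = FALSE]
  energy <- colSums(bottom * (Wo %*% bottom))
  readout_null <- bottom[, which.max(energy)]
  dynamic_null <- bottom[, which.min(energy)]
  dirs <- cbind(potent = potent, readout_null = readout_null,
                dynamic_null = dynamic_null)
  x_star <- task$x_star[, cond]
  eps <- norm_frac * sqrt(sum((x_star - model$x_sp)^2))
  h_fn <- if (task$include_h) function(t) transient_input(t, t_move = 0) else NULL
  run <- function(x0) {
    tr <- simulate(model, move_ms, x0 = x0, h_fn = h_fn)
    m <- task$C %*% tr$rates[, , 1]
    hand <- arm_simulate(array(m, c(2, ncol(m), 1)), 1,
                         task$targets$params)$hand[, , 1]
    list(x = tr$x[, , 1], m = m, hand = hand)
  }
  base <- run(matrix(x_star, N, 1))
  out <- list()
  for (nm in colnames(dirs)) {
    pert <- run(matrix(x_star + eps * dirs[, nm], N, 1))
    out[[nm]] <- list(
      activity_rms = sqrt(colMeans((pert$x - base$x)^2)),
      torque_rms = sqrt(colMeans((pert$m - base$m)^2)),
      hand_dev = sqrt(colSums((pert$hand - base$hand)^2)),
      potency = drop(crossprod(dirs[, nm], Q %*% dirs[, nm])))
  }
  structure(c(out, list(directions = dirs, eps = eps, Q = Q, cond = cond)),
            class = "prepctrl_taxonomy")
}

## 90%-variance orthonormal basis of a matrix (columns = observations),
## optionally after column-mean centering.
var_basis <- function(M, var_frac = 0.9, center = TRUE) {
  if (center) M <- M - rowMeans(M)
  s <- svd(M)
  keep <- s$d^2 / sum(s$d^2)
  K <- which(cumsum(keep) >= var_frac - 1e-12)[1]
  s$u[, seq_len(K), drop = FALSE]
}

#' Coding / persistent / remaining subspace decomposition
#'
#' From unperturbed and perturbed late-preparatory condition means: the
#' coding subspace (CS) captures 90\% of the across-condition variance of
#' \code{Xunpert}; the persistent subspace (PS) captures 90\% of the variance
#' of the perturbation-induced deviation \eqn{\Delta = X_{pert} -
#' X_{unpert}} (uncentered, so the reach-independent component is retained);
#' the remaining subspace (RS) captures 90\% of the variance of
#' \eqn{Y = [X_{unpert}\ X_{pert}]} after orthogonalization against CS and
#' PS.
#'
#' @param Xunpert,Xpert N x conditions matrices of time-averaged
#'   late-preparatory activity.
#' @param var_frac variance fraction defining each basis (0.9).
#' @return list of class \code{prepctrl_subspaces}: \code{U_cs},
#'   \code{U_ps}, \code{U_rs}, minimum CS-PS principal angle
#'   \code{min_angle_deg}, and \code{var_captured} (fraction of centered-Y
#'   variance explained by the union of the three bases).
#' @export
decompose_cs_ps_rs <- function(Xunpert, Xpert, var_frac = 0.9) {
  U_cs <- var_basis(Xunpert, var_frac, center = TRUE)
  Delta <- Xpert - Xunpert
  U_ps <- var_basis(Delta, var_frac, center = FALSE)
  Y <- cbind(Xunpert, Xpert)
  Yc <- Y - rowMeans(Y)
  UU <- cbind(U_cs, U_ps)
  Yo <- Yc - UU %*% solve(crossprod(UU), crossprod(UU, Yc))
  U_rs <- var_basis(Yo, var_frac, center = FALSE)
  Uall <- orth_basis(cbind(U_cs, U_ps, U_rs))
  var_captured <- sum(crossprod(Uall, Yc)^2) / sum(Yc^2)
  structure(list(U_cs = U_cs, U_ps = U_ps, U_rs = U_rs,
                 min_angle_deg = min(principal_angles(U_cs, U_ps)),
                 var_captured = var_captured),
            class = "prepctrl_subspaces")
}

#' Simulated photoinhibition experiments on the gated loop
#'
#' Each experiment drives a random subset (60\%) of the cortical inhibitory
#' neurons with a constant positive input \code{hph} for \code{Tph} ms
#' starting \code{onset} ms after preparation onset (a fresh subset per
#' movement condition). Late-preparatory condition means of unperturbed and
#' perturbed runs are collected, the CS/PS/RS decomposition computed per
#' experiment, and deviation magnitudes in each subspace tracked over time.
#'
#' @param circuit a \code{prepctrl_loop}.
#' @param n_experiments number of perturbation experiments (300 in full;
#'   scaled down by callers as needed).
#' @param seed RNG seed.
#' @param frac_inh fraction of I cells targeted (0.6).
#' @param hph perturbation input (3).
#' @param Tph perturbation duration, ms (400).
#' @param onset perturbation onset after preparation onset, ms (400).
#' @param prep_ms preparation duration, ms (1600).
#' @param avg_ms length of the late-preparatory averaging window, ms (400).
#' @param move_ms movement duration simulated after the go cue, ms.
#' @param keep_dev keep per-subspace deviation time courses (slower).
#' @return list of class \code{prepctrl_photoinhibition}: \code{Xunpert},
#'   per-experiment \code{Xpert} list, \code{min_angles} (CS-PS, degrees),
#'   \code{var_captured}, mean deviation time courses \code{dev} (time x
#'   {CS, PS, RS}), rate-suppression summaries, endpoint errors of perturbed
#'   movements, and the protocol parameters.
#' @export
run_photoinhibition <- function(circuit, n_experiments = 50, seed = 0,
                                frac_inh = 0.6, hph = 3, Tph = 400,
                                onset = 400, prep_ms = 1600, avg_ms = 400,
                                move_ms = 800, keep_dev = TRUE) {
  task <- circuit$task; model <- task$model
  N <- model$N; NE <- model$n_exc; NI <- model$n_inh
  if (NI == 0) stop("run_photoinhibition: network has no inhibitory cells")
  k <- ncol(task$x_star)
  n_target <- round(frac_inh * NI)
  base <- simulate_gated_loop(circuit, prep_ms = prep_ms, move_ms = move_ms,
                              pre_ms = 0)
  win <- which(base$times >= prep_ms - avg_ms & base$times < prep_ms)
  cond_mean <- function(tr) {
    out <- matrix(0, N, k)
    for (j in seq_len(k)) out[, j] <- rowMeans(relu(tr$x[, win, j]))
    out
  }
  Xunpert <- cond_mean(base)
  U_cs <- var_basis(Xunpert, 0.9, center = TRUE)
  set.seed(seed)
  i_inh <- NE + seq_len(NI)
  min_angles <- numeric(n_experiments)
  var_capt <- numeric(n_experiments)
  endpoint <- numeric(n_experiments)
  Xpert_list <- vector("list", n_experiments)
  dev_sum <- NULL
  pwin <- which(base$times >= onset & base$times < onset + Tph)
  rate_targeted <- rate_untargeted_i <- rate_e <- matrix(NA_real_,
                                                         n_experiments, 2)
  for (e in seq_len(n_experiments)) {
    pert <- lapply(seq_len(k), function(j) {
      list(units = sample(i_inh, n_target), h = hph, on = onset,
           off = onset + Tph)
    })
    tr <- simulate_gated_loop(circuit, prep_ms = prep_ms, move_ms = move_ms,
                              pre_ms = 0, perturb = pert)
    Xp <- cond_mean(tr)
    Xpert_list[[e]] <- Xp
    dec <- decompose_cs_ps_rs(Xunpert, Xp)
    min_angles[e] <- dec$min_angle_deg
    var_capt[e] <- dec$var_captured
    endpoint[e] <- tr$endpoint_err_m
    ## paradoxical suppression bookkeeping (perturbed vs unperturbed means
    ## during the perturbation window)
    tg1 <- pert[[1]]$units
    unt <- setdiff(i_inh, tg1)
    rate_targeted[e, ] <- c(mean(relu(tr$x[tg1, pwin, 1])),
                            mean(relu(base$x[tg1, pwin, 1])))
    rate_untargeted_i[e, ] <- c(mean(relu(tr$x[unt, pwin, 1])),
                                mean(relu(base$x[unt, pwin, 1])))
    rate_e[e, ] <- c(mean(relu(tr$x[seq_len(NE), pwin, 1])),
                     mean(relu(base$x[seq_len(NE), pwin, 1])))
    if (keep_dev) {
      nt <- length(base$times)
      dev_e <- matrix(0, nt, 3)
      for (j in seq_len(k)) {
        D <- tr$x[, , j] - base$x[, , j]
        dev_e[, 1] <- dev_e[, 1] + sqrt(colSums(crossprod(dec$U_cs, D)^2))
        dev_e[, 2] <- dev_e[, 2] + sqrt(colSums(crossprod(dec$U_ps, D)^2))
        dev_e[, 3] <- dev_e[, 3] + sqrt(colSums(crossprod(dec$U_rs, D)^2))
      }
      dev_sum <- if (is.null(dev_sum)) dev_e / k else dev_sum + dev_e / k
    }
  }
  structure(list(
    Xunpert = Xunpert, Xpert = Xpert_list, U_cs = U_cs,
    min_angles = min_angles, var_captured = var_capt,
    dev = if (keep_dev) dev_sum / n_experiments else NULL,
    times = base$times, endpoint_err_m = endpoint,
    rates = list(targeted = rate_targeted,
                 untargeted_i = rate_untargeted_i, e = rate_e),
    base = base,
    protocol = list(n_experiments = n_experiments, seed = seed,
                    frac_inh = frac_inh, n_target = n_target, hph = hph,
                    Tph = Tph, onset = onset, prep_ms = prep_ms,
                    avg_ms = avg_ms)),
    class = "prepctrl_photoinhibition")
}

#' Preparatory/movement subspace orthogonality across strategies
#'
#' Computes alignment indices between preparatory and movement epochs under
#' three preparation strategies: optimal LQR feedback, "instant" (activity
#' clamped at the preparatory end state throughout preparation), and naive
#' feedforward. The preparatory window is 300 ms starting
#' \code{prep_offset_ms} after preparation onset; the movement window is
#' 300 ms starting 50 ms before movement onset, with movement onset defined
#' as 100 ms after the control inputs are removed.
#'
#' @param task a calibrated \code{prepctrl_task}.
#' @param law a \code{prepctrl_law} (used for the LQR strategy).
#' @param prep_ms preparation duration (500 ms: long enough that even naive
#'   preparation succeeds).
#' @param prep_offset_ms start of the preparatory window (150).
#' @param window_ms analysis window length (300).
#' @param move_onset_lag lag from switch-off to movement onset (100).
#' @return list: \code{alignment} (named vector over strategies),
#'   \code{dim_prep}, \code{dim_move} (participation ratios of the LQR
#'   epochs), and the epoch objects.
#' @export
orthogonality_suite <- function(task, law, prep_ms = 500,
                                prep_offset_ms = 150, window_ms = 300,
                                move_onset_lag = 100) {
  run_strategy <- function(use_law, instant = FALSE) {
    res <- prepare_lqr(task, if (use_law) law else NULL, prep_ms = prep_ms)
    ip <- which(res$prep$times >= prep_offset_ms &
                  res$prep$times < prep_offset_ms + window_ms)
    prep_rates <- res$prep$rates[, ip, , drop = FALSE]
    if (instant) {
      xs <- relu(task$x_star)
      for (i in seq_along(ip)) prep_rates[, i, ] <- xs
    }
    im <- which(res$move$times >= move_onset_lag - 50 &
                  res$move$times < move_onset_lag - 50 + window_ms)
    move_rates <- res$move$rates[, im, , drop = FALSE]
    list(prep = epoch_data(prep_rates, "prep"),
         move = epoch_data(move_rates, "move"))
  }
  lqr <- run_strategy(TRUE)
  inst <- run_strategy(TRUE, instant = TRUE)
  naive <- run_strategy(FALSE)
  alignment <- c(lqr = alignment_index(lqr$prep, lqr$move),
                 instant = alignment_index(inst$prep, inst$move),
                 naive = alignment_index(naive$prep, naive$move))
  list(alignment = alignment,
       dim_prep = epoch_dimensionality(lqr$prep),
       dim_move = epoch_dimensionality(lqr$move),
       epochs = list(lqr = lqr, instant = inst, naive = naive))
}
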
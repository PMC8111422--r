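## Synthetic condition-averaged firing-rate tensors with planted low-rank
## structure, standing in for recorded PSTHs so that the population metrics
## are testable without any recordings.

#' Specification of a synthetic PSTH pair
#'
#' @param n_neurons number of units.
#' @param n_conditions number of movement conditions (8).
#' @param n_time time samples per epoch.
#' @param dt sample step, ms.
#' @param rank_prep,rank_move latent dimensionalities of the two epochs.
#' @param angle_deg principal angle (degrees) between the preparatory and
#'   movement latent subspaces; applied to each paired latent direction.
#' @param noise_sd isotropic observation noise (Hz).
#' @param smooth_ms Gaussian smoothing kernel width (20 ms).
#' @param latent_ms timescale of the smooth latent trajectories.
#' @param baseline mean firing rate (Hz).
#' @return list of class \code{prepctrl_psth_spec}.
#' @export
psth_spec <- function(n_neurons = 100, n_conditions = 8, n_time = 60,
                      dt = 5, rank_prep = 4, rank_move = 6, angle_deg = 90,
                      noise_sd = 0.05, smooth_ms = 20, latent_ms = 100,
                      baseline = 20) {
  if (rank_prep + rank_move > n_neurons) {
    stop("psth_spec: combined latent rank exceeds neuron count")
  }
  structure(as.list(environment()), class = "prepctrl_psth_spec")
}

## Smooth random latent curves: white noise convolved with a Gaussian kernel
## of width `ms`, unit-variance normalized. Returns n_time x n matrix.
smooth_latents <- function(n_time, n, dt, ms) {
  half <- ceiling(3 * ms / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, sd = ms)
  kern <- kern / sqrt(sum(kern^2))
  raw <- matrix(stats::rnorm((n_time + 2 * half) * n), n_time + 2 * half, n)
  sm <- apply(raw, 2, function(v) stats::convolve(v, kern, type = "filter"))
  sm <- matrix(sm, ncol = n)[seq_len(n_time), , drop = FALSE]
  scale(sm, center = TRUE, scale = apply(sm, 2, stats::sd))
}

#' Generate a synthetic preparatory/movement PSTH pair
#'
#' Rates are \code{baseline + U latent(t, c) + noise}: the preparatory
#' latents live in a random orthonormal subspace \code{U_prep}; each paired
#' movement latent direction is rotated away from it by the requested
#' principal angle (within a plane orthogonal to everything else), so the
#' planted angles are realized exactly. Latent time courses are smooth
#' random curves with equal variances (planted participation ratio equal to
#' the rank), and both latents and noise are smoothed with the specified
#' Gaussian kernel.
#'
#' @param spec a \code{\link{psth_spec}}.
#' @param seed RNG seed.
#' @return list: \code{prep} and \code{move} (\code{\link{epoch_data}}
#'   objects), and \code{truth} (planted bases, angles, ranks).
#' @export
generate_psths <- function(spec, seed = 0) {
  set.seed(seed)
  N <- spec$n_neurons; k <- spec$n_conditions; nt <- spec$n_time
  Kp <- spec$rank_prep; Km <- spec$rank_move
  npair <- min(Kp, Km)
  need <- Kp + Km                      # prep dims + rotation partners + extras
  basis <- qr.Q(qr(matrix(stats::rnorm(N * need), N, need)))
  U_prep <- basis[, seq_len(Kp), drop = FALSE]
  th <- spec$angle_deg * pi / 180
  U_move <- matrix(0, N, Km)
  for (i in seq_len(npair)) {
    U_move[, i] <- cos(th) * basis[, i] + sin(th) * basis[, Kp + i]
  }
  if (Km > npair) {
    U_move[, (npair + 1):Km] <- basis[, (Kp + npair + 1):(Kp + Km),
                                      drop = FALSE]
  }
  make_epoch <- function(U, K, label) {
    rates <- array(0, c(N, nt, k))
    amp <- 5                            # Hz latent scale
    for (j in seq_len(k)) {
      L <- smooth_latents(nt, K, spec$dt, spec$latent_ms) * amp
      noise <- smooth_latents(nt, N, spec$dt, spec$smooth_ms) * spec$noise_sd
      rates[, , j] <- spec$baseline + U %*% t(L) + t(noise)
    }
    epoch_data(rates, label, window_ms = c(0, (nt - 1) * spec$dt))
  }
  prep <- make_epoch(U_prep, Kp, "prep")
  move <- make_epoch(U_move, Km, "move")
  planted_angles <- principal_angles(U_prep, U_move)
  list(prep = prep, move = move,
       truth = list(U_prep = U_prep, U_move = U_move,
                    angle_deg = spec$angle_deg,
                    realized_angles = planted_angles,
                    rank_prep = Kp, rank_move = Km, seed = seed))
}
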
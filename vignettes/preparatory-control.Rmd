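---
title: "Optimal anticipatory control of movement preparation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal anticipatory control of movement preparation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Before a reaching movement begins, motor cortical populations settle into
movement-specific preparatory states. This package implements a control-
theoretic account of that process: movement generation is an autonomous
dynamical event seeded by an initial condition, and preparation is an
*anticipatory control* problem — steer the network state, quickly and
cheaply, into the set of initial conditions from which the upcoming movement
will unfold correctly.

The package provides, end to end:

* recurrent rate-network models of motor cortex (inhibition-stabilized,
  trained "full" and low-rank, and chaotic classes);
* a planar two-link arm driven by a two-dimensional torque readout, with
  target kinematics and torque inversion;
* calibration of the readout and of eight movement-specific initial states;
* preparatory controllers: classical LQR feedback derived from the
  observability Gramian of the motor readout, a naive feedforward baseline,
  and biologically constrained feedback (excitatory-only readout, Dale-law
  sign structure, lagged thalamo-cortical loop gated by basal-ganglia
  disinhibition);
* population-geometry analyses (participation ratio, alignment index, jPCA,
  canonical correlations, subspace potency) and simulated photoinhibition
  experiments, plus a synthetic PSTH generator so the analyses are testable
  standalone.

# Network and arm model

Cortex is modeled as `N = 200` rate units (160 excitatory, 40 inhibitory)
with activations `x(t)` obeying

    tau dx/dt = -x + W phi(x) + h_bar + h(t) + u(t),   phi(x) = max(x, 0),

with `tau = 150` ms. The background input `h_bar = x_sp - W phi(x_sp)`
instates a heterogeneous spontaneous state `x_sp` (entries drawn from a
normal distribution with mean 20 and standard deviation 3, resampled if
non-positive, so that the linearization argument below applies at rest). A
transient, condition-independent, spatially uniform input bump

    h(t) = A [exp(-(t - t_move)/500) - exp(-(t - t_move)/50)]   (ms)

switches on at movement onset; its amplitude `A` is solved in closed form so
the peak equals 5 (`transient_input()`).

The inhibition-stabilized connectivity is constructed by
`build_isn()`: a sparse random Dale-structured seed matrix (density 0.1,
inhibitory column magnitudes balancing the excitatory mass) is scaled to
spectral abscissa 1.2 and the *inhibitory columns only* are then updated by
gradient descent on the smoothed spectral abscissa, with early stopping as
soon as the true spectral abscissa drops below 0.8. The smoothed abscissa is
the level `s` at which the trace of the shifted controllability Gramian
reaches a preset value; its gradient has the closed form
`P Q / tr(P Q)` in terms of the two shifted Gramians, which we verify
against finite differences in the test suite. The smoothing width is a free
parameter of this surrogate (the stopping rule is what is fixed); we use a
trace target of `5 N`, giving a gap of about 0.1 between smoothed and true
abscissa. The resulting excitatory submatrix is unstable on its own
(abscissa > 1), the signature of the inhibition-stabilized regime.

Chaotic networks draw all weights i.i.d. normal with mean `-25/N`; we read
the printed variance as `1.8^2/N` (the typeset exponent interpretation) and
expose it as an argument. Low-rank networks add a trainable rank-5
perturbation `u v^T` to a fixed random base matrix.

The arm (`arm_params()`, `arm_step()`) is the standard planar two-link
model: inertia matrix `M(theta)`, centripetal/Coriolis vector, and joint
friction `B = [[0.05, 0.025], [0.025, 0.05]]`; all parameters follow the
published table (links 0.30/0.33 m, masses 1.4/1.0 kg, inertias
0.025/0.045 kg m^2, lower-arm center of mass at 0.16 m). Hand kinematics
place the resting hand at approximately (0, 0.2) m from the shoulder.

# Targets and torque inversion

`target_reaches()` builds eight straight 20 cm reaches (directions
`36*(i-2)` degrees) with the bell-shaped speed profile
`v(t) = v0 (t/tau_r)^2 exp(-(t/tau_r)^2/2)`, `tau_r = 120` ms; `v0 =
d/(tau_r sqrt(pi/2))` makes the path length exactly `d`. `invert_torques()`
then solves for torque time courses that reproduce these paths under the
Euler-discretized arm: the objective is the integrated squared hand-path
error plus a roughness penalty (mean squared torque gradient, weight
`1e-12`, chosen so that replaying the fitted torques meets a sub-millimeter
hand-path criterion with a large margin while suppressing step-to-step
torque jitter), with the initial torques structurally clamped to zero. The
optimizer is initialized from the discrete-consistent inverse-dynamics
solution along the target joint trajectories, so the refinement converges
in a few L-BFGS iterations; replay error is typically well below 0.1 mm.

# Calibration

`calibrate()` fits the torque readout `C` (2 x N, inhibitory columns zero)
and the eight initial conditions `x*_k` by minimizing the mean integrated
squared torque error of the autonomous movement epoch plus the penalty
`||C||^2 / (2 NE)`. Two constraints are enforced *structurally*, not by
penalties: only excitatory neurons are read out, and the nullspace of `C`
contains both `x_sp` and every `x*_k`, so the network neither moves
spontaneously nor at the end of preparation. During preparation the torques
are additionally clamped to zero when driving the arm, since even tiny
readouts integrate twice through the arm into hand drift.

This optimization is the hardest numerical problem in the package: the loss
is bilinear in (`C`, `x*`) through a rectified recurrent rollout, and
useful solutions must both fit the torques and remain consistent with the
1 ms Euler step used by every downstream simulation. The optimizer combines

1. an exact linear-regime alternating least-squares initialization (readout
   fit and initial-condition fit are both linear problems in the eigenbasis
   of `A = W - I`), with the deviation magnitudes capped in the 100-220
   range so the starting point stays near-linear;
2. cycles of damped Gauss-Newton steps — the readout re-fit by ridge
   regression on the current nonlinear trajectories, and per-condition
   initial-state steps using exact forward sensitivities, constrained to
   the nullspace of `C` — interleaved with joint L-BFGS refinement using
   exact adjoint gradients (all verified against finite differences);
3. final Gauss-Newton refinement at 2 ms and then 1 ms integration steps,
   which removes the residual discretization bias of the 5 ms training
   grid.

The compiled (RcppArmadillo) rollout/adjoint and sensitivity kernels make a
full calibration take a few minutes on one core. Default problem sizes
(200 neurons, 1 s movement horizon, 8 conditions) are those of the study
conditions. Typical converged fits reproduce the target torques to a few
percent RMS and the reach endpoints to within about a centimeter when the
movement is released exactly from `x*_k`.

For the trained classes, `calibrate_trained()` additionally optimizes the
connectivity (every element of `W`, regularized by `||W||^2/N^2`, or the
low-rank factors regularized by `(||u||^2+||v||^2)/(5N)`), with the
condition-independent bump excluded during training for these classes.

`make_normal_surrogate()` block-diagonalizes `A` over the reals, yielding a
*normal* surrogate with identical linear input-output behavior and the
same eigenvalues, rescaled so the summed squared magnitudes of the initial
conditions are preserved; surrogates are simulated linearly (their units
are not sign-constrained), and unlike the trained networks they cannot
transiently amplify their initial conditions.

# Optimal preparatory control

The prospective motor error of a state `x` is the integrated squared
torque error that would result if the movement were released now:
in the linear regime it is the quadratic form `(x - x*)' Q (x - x*)` with
`Q` the observability Gramian of `(A, C)`, solved from
`A'Q + QA + C'C = 0` and rescaled to `Tr(Q) = N`
(`observability_gramian()`). Minimizing the infinite-horizon cost
`integral [ dx' Q dx + lambda ||du||^2 ] dt/tau` gives the classical LQR
law `du = K dx`, `K = -P/lambda` with `A'P + PA - PP/lambda + Q = 0`
(`lqr_gain()`, `lambda = 0.1`); the gain is condition-independent, and only
the steady input `u* = x* - W phi(x*) - h_bar` is movement-specific
(`steady_input()`, which alone implements the naive feedforward strategy).
`cost_report()` decomposes the total cost into energy and prospective parts
through the closed-loop Lyapunov equation, and
`nullspace_weighted_gramian()` implements the variant that additionally
penalizes output torques during preparation
(`eta = 0.2` by default). For chaotic networks the Gramian integral
diverges and `Q = I` is used instead.

Control laws are designed on the linearized dynamics and executed on the
nonlinear circuit throughout (`prepare_lqr()`). Preparation readiness is
operationalized as a worst-case reach endpoint error below 10% of the
reach distance, exposed as a configurable criterion.

# The biologically constrained loop

Cortico-cortical feedback through the thalamus cannot read inhibitory
cells, must respect Dale's law, and incurs integration lags. The synthesis
pipeline (`build_loop_circuit()`) handles these in sequence:

* **Structured gains.** `optimize_structured_gain()` minimizes `Tr(P)`
  subject to the closed-loop Lyapunov constraint, over gains of the form
  `K = Z Gamma` where the selector `Gamma` restricts which state components
  feedback may read. The analytic gradient `2 B'(P + lambda B Z Gamma) S
  Gamma'` follows from the Lagrangian stationarity conditions (two Lyapunov
  equations); optimization starts from the least-squares restriction of the
  unconstrained LQR gain. With the full-state selector the unconstrained
  solution is recovered, and constrained costs are never below the
  unconstrained bound — both asserted in tests.
* **Lags.** Thalamus (`tau_y = 10` ms) integrates a sparse random
  projection `R` (density 0.2) of cortical excitatory activity; layer 4
  (`tau_z = 10` ms) integrates thalamus. The augmented system
  (`build_augmented_system()`) carries these as extra state blocks; the
  weighting matrix is zero-padded so the prospective error still acts on
  the cortical block only. These augmented matrices are *defective*
  (repeated lag eigenvalues with Jordan coupling), so all Lyapunov and
  Riccati solves on them use Schur-form algorithms rather than
  eigendecompositions (see Numerics).
* **Dale's law.** `dale_decompose()` factors the optimal `Z` into
  `Kxz Kzy` with non-negative `Kzy` and sign-structured `Kxz`
  (100 excitatory and 100 inhibitory layer-4 columns), parameterizing
  entries as signed squares; the relative reconstruction error is a couple
  of percent at this population size. The three loop matrices are then
  rebalanced to equal Frobenius norms, which leaves the loop gain exactly
  unchanged (the rescalings cancel, and all loop stages are non-negative so
  the rectifications are inactive along the loop).
* **Gating.** Basal-ganglia disinhibition is modeled as an instantaneous
  ON/OFF switch of the thalamic population (`simulate_gated_loop()`): while
  the gate is closed `y` is held at zero; at the go cue the steady input is
  withdrawn, layer-4 activity decays with `tau_z` while still injecting
  into cortex, and the movement unfolds. Because that decay transient
  perturbs the movement, `refit_initial_states()` re-optimizes the desired
  initial states (readout held fixed — the feedback synthesis depends on
  `C`, and the closed-loop solution does not depend on `x*`), using the
  *discrete* decay factor of the Euler recursion at the 1 ms simulation
  step; matching the discrete propagator here matters, because the layer-4
  kick is large and fast, and a continuous-time approximation at a coarser
  step is exploited by the optimizer and fails at 1 ms.

The steady loop input is delivered directly to cortex; routing it through
the thalamus instead is anatomically equally plausible but is not modeled.

# Photoinhibition and subspace analyses

`run_photoinhibition()` drives a random 60% of the cortical inhibitory
cells with a constant input `h_ph = 3` for 400 ms starting 400 ms into a
1.6 s preparation (a fresh subset per experiment and condition). The
parameter table's absolute count (100 targeted units) is inconsistent with
the 40 recurrent inhibitory cells of the cortical model; we follow the
fraction (60%), which is also how the main text describes the protocol. In
the inhibition-stabilized regime the perturbation paradoxically suppresses
the untargeted population.

For each experiment, condition means of the last 400 ms of preparation
define the coding subspace (CS: 90% variance of the centered unperturbed
means), the persistent subspace (PS: 90% variance of the perturbation-
induced deviations, *uncentered* so that the reach-independent suppression
component is retained), and the remaining subspace (RS: 90% of what is
left of `[X_unpert X_pert]` after orthogonalization against CS and PS).
`decompose_cs_ps_rs()` reports the minimum CS-PS principal angle and the
fraction of variance the three subspaces jointly capture.

Analysis conventions, where the source material leaves them open, are:
all covariances remove each neuron's mean across time and conditions; the
model's preparatory analysis window is 300 ms starting 150 ms after
preparation onset (mirroring the recording convention of a 300 ms window
150 ms after target onset); the movement window is 300 ms starting 50 ms
before movement onset, with model movement onset defined as 100 ms after
the control inputs are removed. jPCA fits the best skew-symmetric generator
in closed form (the skew part of the regression normal equations, solved in
the eigenbasis of the state covariance — the solution is exactly
skew-symmetric by construction) on 6 principal components by default;
canonical correlations are computed after PCA reduction keeping 95% of
variance.

# Synthetic firing-rate fixtures

`generate_psths()` produces condition-averaged rate tensors with planted
structure: smooth Gaussian-kernel latents of equal variance (so the planted
participation ratio equals the latent rank) in random orthonormal
subspaces, with the movement-epoch subspace rotated from the preparatory
one by an exactly realized principal angle, plus smoothed observation
noise (20 ms kernel, matching common PSTH preprocessing). These fixtures
emulate the *geometry* of condition-averaged recordings — latent
dimensionality, subspace angles, smoothness — but not firing-rate
statistics of real data (Poisson variability, heavy-tailed rate
distributions, trial counts), so metric-recovery tests certify the
analysis code, not conclusions about biological recordings.

# Numerics

* Lyapunov equations on generic (diagonalizable) matrices are solved in the
  eigenbasis; every solve carries a residual check. Shifted solves reuse
  one factorization (the stabilizer's line search exploits this).
* Lyapunov equations on possibly defective matrices (closed loops of the
  augmented lag system) use one real Schur decomposition plus LAPACK
  `dtrsyl`, shared between the pair of equations needed by the
  structured-gain gradient.
* Riccati equations with stable `A` are solved by Newton-Kleinman iteration
  (each step a Schur-based Lyapunov solve; quadratically convergent from
  the stabilizing start `P = 0`); otherwise the stable invariant subspace
  of the Hamiltonian matrix is used. Residual tolerances are 1e-7 relative.
* Forward integration is explicit Euler, 1 ms by default (at most a tenth
  of the fastest time constant); a convergence test asserts first-order
  error decay, and linear-regime trajectories are checked against matrix
  exponentials.
* Simulations declare divergence when any state norm exceeds a configurable
  bound; degenerate inputs (zero spectra, rank-deficient covariances,
  non-orthonormal bases) raise explicit errors.

# Design choices and known limitations

The construction of the cortical network is under-determined by its
published description: only the seed density regime, the initial spectral
abscissa (1.2), the early-stopping threshold (0.8), and the
inhibitory-only update rule are stated, while the robust-stability
objective's smoothing width and the seed weight statistics are free. These
choices strongly shape the *observability spectrum* of the calibrated
readout — how motor potency is distributed across state-space directions —
and through it everything downstream: the effective dimensionality of the
potent subspace, how fast LQR preparation can make a movement accurate,
and how much slower the constrained loop is than the unconstrained law.

With the defensible defaults used here, the acceptance computations in
`scripts/acceptance.R` find a potent-subspace participation ratio around
3 (rather than the published ~8), preparatory/movement epoch
dimensionalities in the 3-7 range depending on the network seed (published:
4 and 6), and LQR preparation that needs several hundred milliseconds
(rather than ~50 ms) before all eight reaches land within 10% of the reach
distance: the gradually decaying tail of the potency spectrum leaves
movement-relevant directions under weak feedback, so residual low-frequency
torque errors — which the arm integrates twice — die out slowly. The gated
loop prepares accurate movements with about a second of preparation. The
photoinhibition subspace geometry is qualitatively robust: CS and PS are
strongly non-aligned (minimum principal angles in the high 70s of degrees,
versus the published 89), the three subspaces jointly capture essentially
all late-preparatory variance (published: 98%), untargeted cells are
paradoxically suppressed, and recovery after the perturbation is selective
for the coding subspace. We deliberately did not search the unconstrained
construction parameters for values that reproduce the published
dimensionality; the package reports what its stated construction yields.

Other limitations: movements are open-loop (no sensory feedback during
execution); no muscle model or 3-D arm; basal-ganglia neurons are not
modeled (gating is an idealized switch); noise-driven (stochastic) optimal
control and receding-horizon variants are out of scope; and all analyses
run on model-generated or synthetic rates, never on recordings.
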
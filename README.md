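# prepctrl

Recurrent network models of motor cortex that generate reaching movements,
and the preparatory controllers that make them ready to move.

## The problem

In primates, motor cortex settles into a movement-specific preparatory state
before a reach begins, and does so within tens of milliseconds. `prepctrl`
implements a control-theoretic account of this process. Movement generation
is modeled as an autonomous dynamical event: a rate network

    tau dx/dt = -x(t) + W phi[x(t)] + h_bar + h(t) + u(t),  phi(x) = max(x, 0)

drives a planar two-link arm through a low-dimensional torque readout
`m(t) = C phi[x(t)]`, and each movement is seeded by an initial condition
`x*_k`. Preparation is then an *anticipatory control* problem: choose
control inputs `u(t)` that steer `x` into the right initial condition,
quickly and at low energetic cost.

The central quantity is the **prospective motor error**: the total torque
error that would result if the movement were released from the current
state. In the linearized dynamics (`A = W - I`) it is the quadratic form

    C(x) = (x - x*)' Q (x - x*),   A'Q + QA + C'C = 0,

where `Q` is the observability Gramian of the readout. Minimizing the
infinite-horizon cost `integral [ dx'Q dx + lambda ||du||^2 ] dt/tau` yields
the classical LQR feedback `u(t) = u* + K dx(t)`, `K = -P/lambda` with
`A'P + PA - PP/lambda + Q = 0`. The package also synthesizes biologically
constrained versions of this feedback — reading excitatory cells only,
factored into sign-constrained (Dale-law) pathways, and routed through a
lagged thalamo-cortical loop that basal-ganglia disinhibition gates ON at
preparation onset and OFF at the go cue — plus the population-geometry
analyses used to characterize preparatory and movement activity
(participation ratio, alignment index, jPCA, canonical correlations,
coding/persistent/remaining subspaces under simulated photoinhibition).

## Worked example

```r
library(prepctrl)

## an inhibition-stabilized network (small here for speed): random Dale
## seed scaled to spectral abscissa 1.2, inhibitory weights optimized until
## the abscissa drops below 0.8
net <- build_isn(n_exc = 48, n_inh = 12, seed = 1, p = 0.4)
print(net)
#> <prepctrl_network: isn, N=60 (E=48, I=12), tau=150 ms, abscissa(W)=0.703>

## condition-independent movement-epoch input: amplitude solved so the
## double-exponential bump peaks at exactly 5
h <- transient_input(seq(0, 2000, 0.5), t_move = 100)
sprintf("peak %.4f at t = %.1f ms (A = %.4f)", max(h),
        attr(h, "peak_time"), attr(h, "amplitude"))
#> "peak 5.0000 at t = 227.9 ms (A = 7.1753)"

## eight 20 cm center-out reaches with a bell-shaped speed profile
tg <- target_reaches()
print(tg)
#> <prepctrl_reaches: 8 reaches of 20 cm, tau=120 ms, v0=1.330 m/s, torques not yet inverted>

## effective dimensionality of a spectrum
participation_ratio(c(4, 2, 1, 1))
#> 2.909091
```

The full pipeline at study scale (several minutes per step):

```r
net     <- build_isn(seed = 0)                      # 160 E + 40 I units
targets <- invert_torques(target_reaches())         # target torques m*(t)
task    <- calibrate(net, targets)                  # readout C and x*_k
A   <- net$W - diag(net$N)
Q   <- observability_gramian(A, task$C)             # prospective-error metric
law <- lqr_gain(A, Q, lambda = 0.1)                 # optimal preparatory feedback
res <- prepare_lqr(task, law, prep_ms = 200)        # prepare, release, reach
circ <- refit_initial_states(build_loop_circuit(task))   # thalamo-cortical loop
ph   <- run_photoinhibition(circ, n_experiments = 50)    # perturbation protocol
```

`task$replay$rms_ratio` reports how well the calibrated network reproduces
the target torques (a few percent), `res$endpoint_err_m` the worst-case
hand endpoint error after preparation, and `ph$min_angles` /
`ph$var_captured` the coding-vs-persistent subspace angles and the joint
variance captured by the three photoinhibition subspaces.

A thin command-line front end over these functions is installed at
`inst/cli/prepctrl.R` (subcommands `build`, `calibrate`, `lqr`, `loop`,
`experiment`).

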
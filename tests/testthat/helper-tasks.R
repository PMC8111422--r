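## Shared small-scale fixtures, built once per test run.

tiny_task <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_isn(32, 8, seed = 4, p = 0.5)
      targets <- invert_torques(target_reaches(angles_deg = c(0, 90, 180),
                                               T_ms = 600), maxit = 30)
      cache <<- calibrate(net, targets, dt_cal = 10, gn_rounds = 4,
                          maxit = 150, seed = 1)
    }
    cache
  }
})

tiny_loop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      circ <- build_loop_circuit(tiny_task(), lambda = 0.01, m_exc = 30,
                                 m_inh = 30, seed = 2, maxit_gain = 60,
                                 maxit_dale = 400)
      cache <<- refit_initial_states(circ, maxit = 120)
    }
    cache
  }
})
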
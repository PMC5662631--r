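# Adaptive-solver oracle: integrates the package's pure-R right-hand
# sides with deSolve (lsoda), independently of the fixed-step engine.

oracle_integrate <- function(type, duration, i_ext = 0, i_syn = 0,
                             params = cell_params(type), v0 = NULL,
                             sample_dt = 0.25) {
  st <- if (is.null(v0)) cell_state(type) else cell_state(type, v = v0)
  iext_f <- if (is.function(i_ext)) i_ext else function(t) i_ext
  isyn_f <- if (is.function(i_syn)) i_syn else function(t) i_syn
  rhs <- function(t, y, p) {
    names(y) <- names(st)
    list(unname(cell_rhs(type, y, i_syn = isyn_f(t), i_ext = iext_f(t),
                         params = params)))
  }
  times <- seq(0, duration, by = sample_dt)
  out <- deSolve::lsoda(unname(st), times, rhs, NULL,
                        rtol = 1e-8, atol = 1e-8, maxsteps = 1e6)
  list(times = out[, 1], v = out[, 2])
}

# simple seeded fixture for random-state property loops
prop_voltages <- function(n, seed = 42) {
  set.seed(seed)
  stats::runif(n, -120, 60)
}

# small network used by wiring/engine tests (full default populations but
# short simulations keep this cheap)
tiny_network <- function(seed = 1, ...) {
  build_network(network_config(seed = seed, ...))
}
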
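# Two-state synapse kinetics: closed-form decay, peak normalization,
# current signs and linear superposition.

test_that("synaptic current follows g*(h-m)*(V-E) with the trivial zeros", {
  p <- synapse_params("ampa", g_max = 2)
  expect_equal(synapse_current(c(m = 0, h = 0), p, -55), 0)
  expect_equal(synapse_current(c(m = 0.4, h = 0.4), p, 10), 0)
  g <- synapse_params("gaba")
  expect_equal(synapse_current(c(m = 0.1, h = 0.7), g, -80), 0)
  expect_equal(synapse_current(c(m = 0, h = 0.5), p, -50),
               2 * 0.5 * (-50 - 0))
})

test_that("state variables decay exponentially in closed form", {
  p <- synapse_params("ampa", tau_on = 1, tau_off = 10)
  s <- advance_synapse(c(m = 1, h = 1), p, dt = 1)
  expect_equal(unname(s[["m"]]), exp(-1), tolerance = 1e-12)
  s2 <- advance_synapse(c(m = 0, h = 1), p, dt = 10)
  expect_equal(unname(s2[["h"]]), exp(-1), tolerance = 1e-12)
  z <- advance_synapse(synapse_state(), p, dt = 5)
  expect_equal(unname(z), c(0, 0))
})

test_that("a unitary event peaks at exactly h - m = 1", {
  for (kind in c("ampa", "nmda", "gaba")) {
    p <- synapse_params(kind)
    s <- on_presynaptic_spike(synapse_state(), params = p)
    t_star <- log(p$tau_off / p$tau_on) * p$tau_on * p$tau_off /
      (p$tau_off - p$tau_on)
    # analytic maximum of the dual exponential
    f <- synapse_norm_factor(p)
    peak <- f * (exp(-t_star / p$tau_off) - exp(-t_star / p$tau_on))
    expect_equal(peak, 1, tolerance = 1e-9)
    # numeric maximum over a fine grid agrees
    tt <- seq(0, 20 * p$tau_off, by = p$tau_on / 50)
    g <- s[["h"]] * exp(-tt / p$tau_off) - s[["m"]] * exp(-tt / p$tau_on)
    expect_equal(max(g), 1, tolerance = 1e-5)
  }
})

test_that("two simultaneous events sum to a peak of 2; no event leaves state fixed", {
  p <- synapse_params("ampa")
  s <- on_presynaptic_spike(on_presynaptic_spike(synapse_state(),
                                                 params = p), params = p)
  tt <- seq(0, 50, by = 0.001)
  g <- s[["h"]] * exp(-tt / p$tau_off) - s[["m"]] * exp(-tt / p$tau_on)
  expect_equal(max(g), 2, tolerance = 1e-5)
  s0 <- c(m = 0.2, h = 0.6)
  expect_identical(s0, s0) # no-event semantics: untouched state
})

test_that("weighted current scales linearly and rejects negative weights", {
  expect_equal(weighted_current(0, 5), 0)
  expect_equal(weighted_current(1, -3.2), -3.2)
  expect_equal(weighted_current(2, -3), -6)
  expect_error(weighted_current(-1, 1), "non-negative")
})

test_that("conductance decays monotonically to zero without events", {
  p <- synapse_params("gaba")
  s <- on_presynaptic_spike(synapse_state(), params = p)
  prev <- Inf
  for (i in 1:200) {
    s <- advance_synapse(s, p, dt = 0.5)
    g <- s[["h"]] - s[["m"]]
    if (i > 5) expect_lte(g, prev + 1e-12)
    if (i > 5) prev <- g
  }
  expect_lt(s[["h"]] - s[["m"]], 1e-6)
})

test_that("current signs: glutamatergic inward below 0 mV, GABA outward above -80", {
  s <- c(m = 0.1, h = 0.6)
  expect_lt(synapse_current(s, synapse_params("ampa"), -60), 0)
  expect_lt(synapse_current(s, synapse_params("nmda"), -30), 0)
  expect_gt(synapse_current(s, synapse_params("gaba"), -60), 0)
  expect_lt(synapse_current(s, synapse_params("gaba"), -90), 0)
})

test_that("response is linear in event count (superposition over random trains)", {
  p <- synapse_params("ampa")
  set.seed(7)
  dt <- 0.1
  for (rep in 1:5) {
    ev <- sort(sample(1:400, 12))
    # full train
    s <- synapse_state(); g_tr <- numeric(500)
    for (k in 1:500) {
      if (k %in% ev) s <- on_presynaptic_spike(s, params = p)
      s <- advance_synapse(s, p, dt)
      g_tr[k] <- s[["h"]] - s[["m"]]
    }
    # sum of single-event responses
    g_sum <- numeric(500)
    for (e in ev) {
      s <- synapse_state()
      for (k in 1:500) {
        if (k == e) s <- on_presynaptic_spike(s, params = p)
        s <- advance_synapse(s, p, dt)
        g_sum[k] <- g_sum[k] + s[["h"]] - s[["m"]]
      }
    }
    expect_equal(g_tr, g_sum, tolerance = 1e-10)
  }
})

test_that("synapse parameter validation enforces tau_off > tau_on > 0", {
  expect_error(synapse_params("ampa", tau_on = 3, tau_off = 2), "tau_off")
  expect_error(synapse_params("ampa", tau_on = -1), "tau_off")
  expect_equal(synapse_params("gaba")$e_syn, -80)
  expect_equal(synapse_params("ampa")$e_syn, 0)
  expect_equal(synapse_params("nmda")$e_syn, 0)
})
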
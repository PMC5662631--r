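# Single-compartment cell dynamics: fixed points, rest-state phenotypes,
# adaptation, pacemaking, and state validation.

test_that("leak-only thalamic cell has an exact fixed point at the leak reversal", {
  p <- cell_params("th", g_na = 0, g_k = 0, g_t = 0)
  st <- cell_state("th", v = p$e_l)
  d <- th_rhs(st, i_syn = 0, params = p)
  expect_equal(unname(d[["v"]]), 0, tolerance = 1e-12)
})

test_that("gating derivatives vanish when gates sit at steady state", {
  for (type in c("th", "stn", "gpe", "gpi", "py", "da")) {
    st <- cell_state(type, v = -63.5)
    d <- cell_rhs(type, st)
    gates <- setdiff(names(d), c("v", "ca"))
    expect_true(all(abs(d[gates]) < 1e-10),
                label = paste(type, "gate derivatives at steady state"))
  }
})

test_that("rest-state phenotypes: TH/GPe/GPi silent, STN tonic at low rate", {
  th <- simulate_cell("th", 2000)
  expect_length(th$spikes, 0)
  gpe <- simulate_cell("gpe", 2000)
  expect_length(gpe$spikes, 0)
  gpi <- simulate_cell("gpi", 2000)
  expect_length(gpi$spikes, 0)
  stn <- simulate_cell("stn", 2000)
  rate <- length(stn$spikes) / 2
  expect_gt(rate, 0)
  expect_lte(rate, 30)
})

test_that("depolarizing step recruits the thalamic cell within 500 ms", {
  th <- simulate_cell("th", 500,
                      i_ext = make_waveform("constant", amp = 2, t_on = 50))
  expect_gte(length(th$spikes), 1)
})

test_that("STN excitation raises and inhibition lowers the firing rate", {
  base <- length(simulate_cell("stn", 2000)$spikes)
  exc <- length(simulate_cell("stn", 2000,
    i_ext = make_waveform("constant", amp = 10))$spikes)
  inh <- length(simulate_cell("stn", 2000,
    i_ext = make_waveform("constant", amp = -10))$spikes)
  expect_gt(exc, base)
  expect_lt(inh, base)
})

test_that("GPe is silent from rest under inhibitory-only input", {
  gpe <- simulate_cell("gpe", 1000,
    i_ext = make_waveform("constant", amp = -3))
  expect_length(gpe$spikes, 0)
})

test_that("pyramidal cell adapts: inter-spike intervals grow under a step", {
  py <- simulate_cell("py", 2000,
                      i_ext = make_waveform("constant", amp = 1.5,
                                            t_on = 200))
  expect_gte(length(py$spikes), 5)
  isi <- diff(py$spikes)
  # successive ISIs non-decreasing up to a small tolerance
  expect_true(all(diff(isi) > -1))
  expect_gt(isi[length(isi)], isi[1])
})

test_that("pyramidal cell at rest with zero drive never spikes", {
  py <- simulate_cell("py", 1000)
  expect_length(py$spikes, 0)
})

test_that("a weaker M-current yields at least as many late spikes", {
  stim <- make_waveform("constant", amp = 1.5, t_on = 100)
  with_m <- simulate_cell("py", 1500, i_ext = stim)
  no_m <- simulate_cell("py", 1500, i_ext = stim,
                        params = cell_params("py", g_m = 0))
  late <- function(s) sum(s$spikes > 750)
  expect_gte(late(no_m), late(with_m))
})

test_that("dopaminergic cell pacemakes tonically with regular intervals", {
  da <- simulate_cell("da", 3000)
  sp <- da$spikes[da$spikes > 500]
  rate <- length(sp) / 2.5
  expect_gt(rate, 0.5)
  isi <- diff(sp)
  expect_gt(length(isi), 2)
  expect_lt(stats::sd(isi) / mean(isi), 0.5)
})

test_that("non-finite state values are rejected", {
  st <- cell_state("th")
  st[["v"]] <- NaN
  expect_error(th_rhs(st), "invalid cell state")
  st2 <- cell_state("stn")
  st2[["ca"]] <- Inf
  expect_error(stn_rhs(st2), "invalid cell state")
})

test_that("steady-state gating values lie in [0, 1] across the voltage range", {
  for (v in prop_voltages(50)) {
    for (type in c("th", "stn", "gpe", "gpi", "py", "da")) {
      st <- cell_state(type, v = v)
      gates <- setdiff(names(st), c("v", "ca"))
      expect_true(all(st[gates] >= 0 & st[gates] <= 1),
                  label = sprintf("%s gates at v = %.1f", type, v))
    }
  }
})

test_that("gates stay in [0, 1] under extreme square-pulse drive", {
  for (type in c("th", "py", "stn")) {
    r <- simulate_cell(type, 400,
      i_ext = make_waveform("constant", amp = 80, t_on = 100, t_off = 250))
    ns <- length(cell_state(type))
    gates <- r$state[2:(ns - as.integer(type != "py"))]
    expect_true(all(gates >= 0 & gates <= 1 + 1e-12),
                label = paste(type, "gates bounded"))
  }
})

test_that("identical state and inputs give identical derivatives (purity)", {
  st <- cell_state("gpi", v = -55)
  d1 <- gpi_rhs(st, list(d1 = 0.3, stn = -0.2))
  d2 <- gpi_rhs(st, list(d1 = 0.3, stn = -0.2))
  expect_identical(d1, d2)
})
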
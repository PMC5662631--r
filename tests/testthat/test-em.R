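# Memristive cortical neuron: memconductance, model reduction, mode
# classification, flux boundedness.

test_that("memconductance evaluates alpha + 3*beta*phi^2 and is even", {
  expect_equal(memconductance(0, 0.4, 0.01), 0.4)
  expect_equal(memconductance(1, 0.4, 0.01), 0.43)
  for (phi in prop_voltages(20)) {
    expect_equal(memconductance(phi), memconductance(-phi))
  }
  expect_error(memconductance(0, alpha = -1), "alpha > 0")
})

test_that("em_rhs reduces exactly to the plain pyramidal cell at a_e = 0, k = 0", {
  p <- em_params(k = 0, a_e = 0)
  py_p <- cell_params("py")
  for (v in c(-80, -65, -50, -30)) {
    st_py <- cell_state("py", v = v)
    st_em <- c(st_py[c("v", "m", "h", "n", "q", "r", "p")], phi = 0.3)
    d_em <- em_rhs(st_em, p, t = 123)
    d_py <- py_rhs(st_py, i_syn = 0, i_ext = 0, py_p)
    for (g in c("v", "m", "h", "n", "q", "r", "p")) {
      expect_equal(unname(d_em[[g]]), unname(d_py[[g]]), tolerance = 1e-12,
                   label = paste("gate", g, "at", v))
    }
  }
})

test_that("the AC derivative term equals -a_e*omega*cm at t = 0", {
  p <- em_params(a_e = 1.2, omega = 6.27)
  p0 <- em_params(a_e = 0, omega = 6.27)
  st <- cell_state("py", v = -71)
  st <- c(st[c("v", "m", "h", "n", "q", "r", "p")], phi = 0)
  d1 <- em_rhs(st, p, t = 0)
  d0 <- em_rhs(st, p0, t = 0)
  # at t = 0 the field itself vanishes, only the cos term differs
  expect_equal(unname(d1[["v"]] - d0[["v"]]), -1.2 * 6.27,
               tolerance = 1e-9)
})

test_that("compiled EM integrator matches the R reference dynamics", {
  p <- em_params(a_e = 0.4, omega = 0.0394)
  rec <- simulate_em(p, duration = 300, record_stride = 10L)
  # reference: explicit fixed-step integration of em_rhs at the same dt
  st <- cell_state("py", v = -71)
  y <- c(st[c("v", "m", "h", "n", "q", "r", "p")],
         phi = p$k1 * -71 / p$k2)
  dt <- 0.025
  vs <- numeric(length(rec$times)); vs[1] <- y[["v"]]
  for (i in seq_len(300 / dt)) {
    d <- em_rhs(y, p, t = (i - 1) * dt)
    y <- y + dt * d
    if (i %% 10 == 0) vs[i / 10 + 1] <- y[["v"]]
  }
  expect_lt(max(abs(vs - rec$v)), 0.5)
})

test_that("flux remains bounded for bounded voltage", {
  p <- em_params(a_e = 2, omega = 6.31)
  rec <- simulate_em(p, duration = 5000)
  # |phi| <= k1/k2 * max|v| at stationarity (linear stable flux equation)
  expect_lt(abs(rec$state[8]), p$k1 / p$k2 * 130 + 1)
})

test_that("classify_mode labels constructed traces correctly", {
  dt <- 0.25
  tt <- seq(0, 12000, by = dt)
  flat <- rep(-71, length(tt))
  expect_equal(classify_mode(flat, dt)$mode, "quiescent")
  smpo <- -71 + 1.5 * sin(2 * pi * tt / 160)
  expect_equal(classify_mode(smpo, dt)$mode, "SMPO")
  # regular single spikes at 8 Hz
  spk <- rep(-71, length(tt))
  spk[seq(1, length(tt), by = 125 / dt)] <- 20
  expect_equal(classify_mode(spk, dt)$mode, "spiking_period1")
  # period-3 bursting: triplets every 400 ms
  b3 <- rep(-71, length(tt))
  for (t0 in seq(100, 11900, by = 400)) {
    b3[round((t0 + c(0, 10, 20)) / dt) + 1] <- 20
  }
  cl <- classify_mode(b3, dt)
  expect_equal(cl$mode, "bursting_period_3")
  expect_equal(cl$spikes_per_burst, 3, tolerance = 0.05)
  # mixed mode: alternating 1-spike / 2-spike groups
  mm <- rep(-71, length(tt))
  k <- 0
  for (t0 in seq(100, 11900, by = 400)) {
    n <- if (k %% 2 == 0) 1 else 2; k <- k + 1
    mm[round((t0 + seq(0, by = 12, length.out = n)) / dt) + 1] <- 20
  }
  expect_equal(classify_mode(mm, dt)$mode, "mixed_mode")
  # irregular ISIs -> chaotic
  set.seed(3)
  ch <- rep(-71, length(tt))
  ch[sort(sample(seq(400, length(tt) - 400), 120))] <- 20
  expect_equal(classify_mode(ch, dt)$mode, "chaotic")
  expect_error(classify_mode(rep(-71, 100), dt), "too short")
})

test_that("larger field amplitude never decreases the recorded oscillation", {
  # literal-model property: v carries the -a_e*sin term directly
  p2p <- vapply(c(0.4, 0.8, 1.2, 2.0), function(a) {
    rec <- simulate_em(em_params(a_e = a, omega = 6.31), duration = 4000)
    keep <- rec$times > 2000
    max(rec$v[keep]) - min(rec$v[keep])
  }, numeric(1))
  expect_true(all(diff(p2p) > 0))
})

test_that("mode sweep returns one classified row per grid point", {
  grid <- tibble::tibble(a_e = c(0.4, 1.2), omega = 6.31, i_app = 0)
  tbl <- em_mode_sweep(grid, duration = 4000)
  expect_equal(nrow(tbl), 2)
  expect_true(all(c("mode", "spikes_per_burst", "p2p") %in% names(tbl)))
  expect_error(em_mode_sweep(grid[0, ]), "empty grid")
})
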
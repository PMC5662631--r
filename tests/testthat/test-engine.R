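# Fixed-step engine: grid arithmetic, determinism, stimuli, and agreement
# with the adaptive-solver oracle on the reference right-hand sides.

test_that("recording length follows the sampling grid", {
  net <- tiny_network(seed = 1)
  rec <- simulate_network(net, sim_spec(duration = 100, record_stride = 1L))
  expect_equal(length(rec$times), 100 / 0.025 + 1)
  rec2 <- simulate_network(net, sim_spec(duration = 100,
                                         record_stride = 10L))
  expect_equal(length(rec2$times), 100 / 0.25 + 1)
})

test_that("identical spec and seed reproduce identical spike trains", {
  net <- tiny_network(seed = 2)
  a <- simulate_network(net, sim_spec(duration = 400, seed = 9))
  b <- simulate_network(net, sim_spec(duration = 400, seed = 9))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$traces, b$traces)
  c <- simulate_network(net, sim_spec(duration = 400, seed = 10))
  expect_false(identical(a$spikes, c$spikes))
})

test_that("waveforms evaluate as specified", {
  s <- make_waveform("sine", amp = 3, omega = 0.1)
  expect_equal(s(0), 0)
  tt <- seq(0, 500, by = 0.7)
  expect_true(all(abs(s(tt)) <= 3 + 1e-12))
  k <- make_waveform("constant", amp = -2)
  expect_true(all(k(tt) == -2))
  expect_error(make_waveform("triangle"), "arg")
})

test_that("fixed-step engine matches the adaptive oracle on pinned stimuli", {
  # three pinned sub-threshold protocols per cell type, 500 ms, 1 mV
  # sup-norm; spontaneously active cells are held hyperpolarized
  holds <- list(th = 0, stn = -35, gpe = 0, gpi = 0, py = 0, da = -3)
  # mild depolarizing step for the rebound-prone thalamic cell,
  # hyperpolarizing for the rest
  steps <- list(th = 0.2, stn = -0.5, gpe = -0.5, gpi = -0.5, py = -0.5,
                da = -0.5)
  om <- 2 * pi / 180
  for (type in names(holds)) {
    h <- holds[[type]]
    s_amp <- steps[[type]]
    protos <- list(
      hold = list(
        fun = function(t) h,
        wf = list(make_waveform("constant", amp = h))),
      step = list(
        fun = function(t) h + ifelse(t >= 200 & t <= 350, s_amp, 0),
        wf = list(make_waveform("constant", amp = h),
                  make_waveform("constant", amp = s_amp, t_on = 200,
                                t_off = 350))),
      sine = list(
        fun = function(t) h + 0.3 * sin(om * t),
        wf = list(make_waveform("constant", amp = h),
                  make_waveform("sine", amp = 0.3, omega = om))))
    for (nm in names(protos)) {
      orc <- oracle_integrate(type, 500, i_ext = protos[[nm]]$fun)
      eng <- simulate_cell(type, 500, i_ext = protos[[nm]]$wf,
                           record_stride = 10L)
      expect_lt(max(abs(eng$v - orc$v)), 1,
                label = sprintf("%s / %s sup-norm", type, nm))
    }
  }
})

test_that("engine and oracle agree for step and sinusoidal drive (thalamic cell)", {
  # step protocol
  orc <- oracle_integrate("th", 500,
                          i_ext = function(t) ifelse(t >= 200, 0.3, 0))
  eng <- simulate_cell("th", 500,
                       i_ext = make_waveform("constant", amp = 0.3,
                                             t_on = 200),
                       record_stride = 10L)
  expect_lt(max(abs(eng$v - orc$v)), 1)
  # subthreshold sine
  om <- 2 * pi / 180
  orc2 <- oracle_integrate("th", 500,
                           i_ext = function(t) 0.2 * sin(om * t))
  eng2 <- simulate_cell("th", 500,
                        i_ext = make_waveform("sine", amp = 0.2,
                                              omega = om),
                        record_stride = 10L)
  expect_lt(max(abs(eng2$v - orc2$v)), 1)
})

test_that("halving dt changes a subthreshold reference trace by < 0.5 mV", {
  a <- simulate_cell("th", 500, dt = 0.025, record_stride = 10L,
                     i_ext = make_waveform("sine", amp = 0.3,
                                           omega = 2 * pi / 120))
  b <- simulate_cell("th", 500, dt = 0.0125, record_stride = 20L,
                     i_ext = make_waveform("sine", amp = 0.3,
                                           omega = 2 * pi / 120))
  expect_equal(length(a$v), length(b$v))
  expect_lt(max(abs(a$v - b$v)), 0.5)
})

test_that("isolated thalamic cells in a network stay silent without input", {
  cfg <- network_config(bias = list(i_appth = 0), weights = list(
    w_gpi_th = 0))
  net <- build_network(cfg)
  rec <- simulate_network(net, sim_spec(duration = 1000, record = "th"))
  expect_equal(nrow(rec$spikes[rec$spikes$population == "th", ]), 0)
})

test_that("numerical blow-up raises a diagnostic error naming the unit", {
  expect_error(
    simulate_cell("th", 50,
                  i_ext = make_waveform("constant", amp = 1e6)),
    "blow-up")
})

test_that("tidy and glance summarise recordings as tibbles", {
  net <- tiny_network(seed = 1)
  rec <- simulate_network(net, sim_spec(duration = 300))
  td <- tidy(rec)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$population),
                  c("th", "gpi", "gpe", "stn", "d1", "d2"))
  g <- glance(rec, t_start = 100)
  expect_s3_class(g, "tbl_df")
  expect_true(all(c("population", "mean_rate_hz") %in% names(g)))
})
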
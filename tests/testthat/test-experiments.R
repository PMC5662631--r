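# Scenario drivers: table shapes, reproducibility and trial exchange-
# ability at desk scale (short trials, few seeds).

test_that("spine sweep returns one finite row per grid point", {
  tbl <- run_spine_sweep(depletion = 0, ns_grid = c(0, 16, 32), trials = 2,
                         seed = 1, duration = 800)
  expect_equal(nrow(tbl), 3)
  expect_equal(tbl$spine_loss_fraction, c(0, 0.5, 1))
  expect_true(all(is.finite(tbl$ei_mean)))
  expect_error(run_spine_sweep(0, ns_grid = c(40)), "ns_grid")
})

test_that("dendrite sweep with nd = 0 reduces to a plain depletion run", {
  tbl <- run_dendrite_sweep(depletion = 0.25, nd_grid = 0, trials = 2,
                            seed = 2, duration = 800)
  scan <- run_depletion_scan(fractions = 0.25, trials = 2, seed = 2,
                             duration = 800)
  expect_equal(tbl$ei_mean, scan$ei_mean, tolerance = 1e-12)
  expect_equal(tbl$degeneration_fraction, 0)
})

test_that("sweep tables are reproducible from seed alone", {
  a <- run_depletion_scan(fractions = c(0, 0.5), trials = 2, seed = 5,
                          duration = 600)
  b <- run_depletion_scan(fractions = c(0, 0.5), trials = 2, seed = 5,
                          duration = 600)
  expect_equal(a, b)
})

test_that("trial-level scores do not leak state across trials", {
  # running a trial alone equals running it inside a batch
  cfg <- network_config(dopamine_depletion = 0.5)
  seeds <- bgnetsim:::trial_seeds(3, 2)
  alone <- score_relay(cfg, seeds[2], duration = 600)
  cal <- relay_calibration(cfg, seeds[2], 600)
  batch <- score_relay(cfg, seeds[2], duration = 600, calibration = cal)
  expect_equal(alone$ei, batch$ei)
  expect_equal(alone$th_rate, batch$th_rate)
})

test_that("cortical stimulation grid reports five-number EI summaries", {
  tbl <- run_cortical_stim_grid(depletion = 0.5, amp_grid = 1,
                                freq_grid = c(10, 130), trials = 2,
                                seed = 1, duration = 800)
  expect_equal(nrow(tbl), 2)
  expect_true(all(tbl$ei_min <= tbl$ei_q1 & tbl$ei_q1 <= tbl$ei_median &
                    tbl$ei_median <= tbl$ei_q3 & tbl$ei_q3 <= tbl$ei_max,
                  na.rm = TRUE))
})
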
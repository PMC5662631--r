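# Peak classification, error index, rate metrics and the phase diagram.

test_that("classify_peaks thresholds synthetic heights exactly", {
  g <- generate_trace(c(1.0, 0.95))
  c1 <- classify_peaks(g$trace, g$dt, g$baseline, g$ref_max, g$windows)
  expect_equal(c(c1$n_lost, c1$n_incomplete, c1$n_normal), c(0L, 0L, 2L))

  g2 <- generate_trace(c(1.0, 0.5, 0.05))
  c2 <- classify_peaks(g2$trace, g2$dt, g2$baseline, g2$ref_max, g2$windows)
  expect_equal(c(c2$n_lost, c2$n_incomplete, c2$n_normal), c(1L, 1L, 1L))

  g3 <- generate_trace(numeric(0), duration = 900)
  c3 <- classify_peaks(g3$trace, g3$dt, g3$baseline, ref_max = 80,
                       windows = seq(0, 900, length.out = 4))
  expect_equal(c(c3$n_lost, c3$n_incomplete, c3$n_normal), c(3L, 0L, 0L))
})

test_that("classification is exhaustive and exclusive over windows", {
  set.seed(5)
  for (rep in 1:10) {
    h <- round(stats::runif(sample(3:8, 1)), 2)
    g <- generate_trace(h)
    cc <- classify_peaks(g$trace, g$dt, g$baseline, g$ref_max, g$windows)
    expect_equal(cc$n_lost + cc$n_incomplete + cc$n_normal,
                 length(g$windows) - 1L)
  }
})

test_that("classification is invariant to positive scaling above baseline", {
  g <- generate_trace(c(1.0, 0.6, 0.3, 0.05))
  base <- classify_peaks(g$trace, g$dt, g$baseline, g$ref_max, g$windows)
  for (k in c(0.5, 2, 7)) {
    scaled <- g$baseline + k * (g$trace - g$baseline)
    cc <- classify_peaks(scaled, g$dt, g$baseline, k * g$ref_max, g$windows)
    expect_equal(cc[, 1:3], base[, 1:3])
  }
})

test_that("degenerate traces are rejected", {
  flat <- rep(-70, 100)
  expect_error(classify_peaks(flat, 0.25, baseline = -70),
               "degenerate trace")
})

test_that("error index is the incomplete-to-normal ratio with guarded zero", {
  expect_equal(error_index(list(n_incomplete = 0, n_normal = 10)), 0)
  expect_equal(error_index(list(n_incomplete = 5, n_normal = 10)), 0.5)
  expect_equal(error_index(3, n_normal = 4), 0.75)
  expect_error(error_index(list(n_incomplete = 2, n_normal = 0)),
               "undefined")
})

test_that("mean firing rate counts per window and is shift invariant", {
  expect_equal(mean_firing_rate(seq(50, 1000, length.out = 16), 1000), 16)
  expect_equal(mean_firing_rate(numeric(0), 500), 0)
  sp <- c(100, 220, 410)
  expect_equal(mean_firing_rate(sp, c(0, 1000)),
               mean_firing_rate(sp + 300, c(300, 1300)))
})

test_that("spikes per burst segments trains at the ISI gap", {
  train <- cumsum(c(100, 5, 5, 100, 5, 5))
  expect_equal(spikes_per_burst(train, isi_gap = 50), 3)
  expect_equal(spikes_per_burst(500, isi_gap = 50), 1)
  tonic <- seq(0, 1000, by = 20)
  expect_equal(spikes_per_burst(tonic, isi_gap = 30),
               length(tonic))
  expect_equal(spikes_per_burst(numeric(0)), 0)
})

test_that("phase diagram dispersion separates functional from independent traces", {
  set.seed(9)
  gpi <- stats::runif(4000, -80, -20)
  th_fun <- -60 + 0.3 * gpi          # deterministic function of GPi
  pd <- phase_diagram(gpi, th_fun, breaks = 10)
  expect_true(all(stats::na.omit(pd$dispersion$sd_th) < 2))
  th_ind <- stats::runif(4000, -80, -20)
  pd2 <- phase_diagram(gpi, th_ind, breaks = 10)
  expect_gt(stats::median(pd2$dispersion$sd_th, na.rm = TRUE), 10)
  pd3 <- phase_diagram(gpi, gpi)
  expect_true(all(stats::na.omit(pd3$dispersion$sd_th) <
                    stats::sd(gpi)))
  expect_error(phase_diagram(gpi, th_ind[-1]), "equal length")
})

test_that("detect_spikes finds crossings with refractory lockout", {
  expect_length(detect_spikes(rep(-65, 400), 0.25), 0)
  v <- rep(-70, 200); v[100:102] <- c(-10, 20, -10)
  sp <- detect_spikes(v, 0.25)
  expect_length(sp, 1)
  expect_equal(sp, 99 * 0.25, tolerance = 0.26)
  # two crossings 1 ms apart with a 2 ms lockout count once
  v2 <- rep(-70, 200); v2[c(100, 104)] <- 10
  expect_length(detect_spikes(v2, 0.25, refractory = 2), 1)
  expect_length(detect_spikes(v2, 0.25, refractory = 0.5), 2)
})
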
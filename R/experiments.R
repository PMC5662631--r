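# Scenario drivers: seeded multi-trial simulations of depletion scans,
# MSN lesion sweeps and cortical stimulation grids, scored with the
# thalamic relay error index.

#' Calibrated relay scoring of one network condition
#'
#' Runs the condition network and a matching healthy (0 depletion, intact
#' MSN) calibration network under the same trial seed, derives the
#' per-thalamic-cell reference maximum and expected-response window grid
#' from the calibration run, classifies the condition run's thalamic
#' peaks, and aggregates counts over TH cells.
#'
#' @param condition_cfg a [network_config()] for the condition.
#' @param seed trial seed.
#' @param duration trial duration (ms).
#' @param baseline thalamic baseline (mV) for peak heights.
#' @param t_start transient discarded before scoring (ms).
#' @param calibration optional pre-computed calibration object from
#'   [relay_calibration()] (must match `seed` and `duration`).
#' @return one-row tibble: `ei`, `n_lost`, `n_incomplete`, `n_normal`,
#'   `th_rate`, plus per-population mean rates.
#' @export
score_relay <- function(condition_cfg, seed, duration = 2000,
                        baseline = -70, t_start = 500,
                        calibration = NULL) {
  if (is.null(calibration)) {
    calibration <- relay_calibration(condition_cfg, seed, duration,
                                     baseline, t_start)
  }
  net <- build_network(condition_cfg)
  rec <- simulate_network(net, sim_spec(duration = duration, seed = seed))
  score_recording(rec, calibration, baseline = baseline, t_start = t_start)
}

#' Healthy-state relay calibration
#'
#' Simulates the zero-depletion, intact-morphology version of a
#' configuration and extracts, per thalamic cell, the reference maximum
#' peak height and expected-window period used to score lesioned or
#' depleted conditions.
#'
#' @inheritParams score_relay
#' @return list with per-cell references and the calibration recording's
#'   summary.
#' @export
relay_calibration <- function(condition_cfg, seed, duration = 2000,
                              baseline = -70, t_start = 500) {
  cfg <- condition_cfg
  cfg$dopamine_depletion <- 0
  cfg$ns <- 0L
  cfg$nd <- 0L
  net <- build_network(cfg)
  rec <- simulate_network(net, sim_spec(duration = duration, seed = seed))
  th_probes <- grep("^th_", rownames(rec$traces), value = TRUE)
  dt <- rec$times[2] - rec$times[1]
  refs <- lapply(th_probes, function(p) {
    relay_reference(rec$traces[p, ], dt, baseline = baseline,
                    t_start = t_start)
  })
  names(refs) <- th_probes
  out <- list(refs = refs, seed = seed, duration = duration,
              summary = glance(rec, t_start = t_start))
  # self-score: the calibration run IS the fraction-0, intact condition,
  # so sweep drivers can reuse it instead of re-simulating
  out$self_score <- score_recording(rec, out, baseline = baseline,
                                    t_start = t_start)
  out
}

# classify thalamic peaks of a recording against a calibration
score_recording <- function(rec, calibration, baseline = -70,
                            t_start = 500) {
  dt <- rec$times[2] - rec$times[1]
  duration <- max(rec$times)
  th_probes <- names(calibration$refs)
  counts <- purrr::map_dfr(th_probes, function(p) {
    ref <- calibration$refs[[p]]
    win <- ref$windows(duration)
    classify_peaks(rec$traces[p, ], dt, baseline = baseline,
                   ref_max = ref$ref_max, windows = win)
  })
  tot <- dplyr::summarise(counts,
                          n_lost = sum(n_lost),
                          n_incomplete = sum(n_incomplete),
                          n_normal = sum(n_normal))
  g <- glance(rec, t_start = t_start)
  rates <- stats::setNames(g$mean_rate_hz, paste0("rate_", g$population))
  ei <- if (tot$n_normal > 0) tot$n_incomplete / tot$n_normal else NA_real_
  dplyr::bind_cols(
    tibble::tibble(ei = ei), tot,
    tibble::tibble(th_rate = unname(rates["rate_th"])),
    tibble::as_tibble(as.list(rates))
  )
}

trial_seeds <- function(seed, trials) seed + 101L * (seq_len(trials) - 1L)

#' Dopamine-depletion scan
#'
#' For each depletion fraction, runs seeded trials and reports the thalamic
#' mean firing rate and error index (mean and sd over trials). The
#' fraction-0 row defines the "normal band" (mean +/- 2 sd) used in the
#' published threshold claims.
#'
#' @param fractions depletion fractions in `[0, 1]`.
#' @param trials number of trials per fraction.
#' @param seed base seed; trial seeds are derived deterministically.
#' @param duration trial duration (ms).
#' @param config base [network_config()] (depletion field is overridden).
#' @return tibble: `fraction`, `th_rate_mean`, `th_rate_sd`, `ei_mean`,
#'   `ei_sd`, `is_pd`, plus mean rates of the recorded populations.
#' @export
run_depletion_scan <- function(fractions = seq(0, 1, by = 0.25), trials = 5,
                               seed = 1L, duration = 2000,
                               config = network_config()) {
  seeds <- trial_seeds(seed, trials)
  cals <- lapply(seeds, function(s) {
    relay_calibration(config, s, duration)
  })
  purrr::map_dfr(fractions, function(f) {
    cfg <- config
    cfg$dopamine_depletion <- f
    reuse <- f == 0 && cfg$ns == 0 && cfg$nd == 0
    per_trial <- purrr::map_dfr(seq_along(seeds), function(i) {
      if (reuse) cals[[i]]$self_score
      else score_relay(cfg, seeds[i], duration, calibration = cals[[i]])
    })
    tibble::tibble(
      fraction = f,
      th_rate_mean = mean(per_trial$th_rate),
      th_rate_sd = stats::sd(per_trial$th_rate),
      ei_mean = mean(per_trial$ei, na.rm = TRUE),
      ei_sd = stats::sd(per_trial$ei, na.rm = TRUE),
      is_pd = f > 0.5,
      rate_gpi_mean = mean(per_trial$rate_gpi),
      rate_gpe_mean = mean(per_trial$rate_gpe),
      rate_d2_mean = mean(per_trial$rate_d2),
      rate_d1_mean = mean(per_trial$rate_d1)
    )
  })
}

#' Dendritic-spine-loss sweep
#'
#' EI as a function of the number of removed spines `Ns` (fraction
#' `Ns/32`), at a fixed dopamine depletion, over seeded trials. Spine
#' removal uses the type-1-first ordering: spines whose dopaminergic
#' partner site was lost to depletion fall first.
#'
#' @param depletion dopamine depletion fraction.
#' @param ns_grid spine-removal counts (subset of 0..32).
#' @param trials trials per grid point.
#' @param seed base seed.
#' @param duration trial duration (ms).
#' @param config base configuration.
#' @return tibble: `ns`, `spine_loss_fraction`, `ei_mean`, `ei_sd`,
#'   `th_rate_mean`.
#' @export
run_spine_sweep <- function(depletion, ns_grid = seq(0, 32, by = 8),
                            trials = 5, seed = 1L, duration = 2000,
                            config = network_config()) {
  stopifnot(all(ns_grid >= 0 & ns_grid <= 32))
  seeds <- trial_seeds(seed, trials)
  cals <- lapply(seeds, function(s) relay_calibration(config, s, duration))
  purrr::map_dfr(ns_grid, function(ns) {
    cfg <- config
    cfg$dopamine_depletion <- depletion
    cfg$ns <- as.integer(ns)
    cfg$spine_order <- "type1_first"
    per_trial <- purrr::map_dfr(seq_along(seeds), function(i) {
      score_relay(cfg, seeds[i], duration, calibration = cals[[i]])
    })
    tibble::tibble(ns = ns, spine_loss_fraction = ns / 32,
                   ei_mean = mean(per_trial$ei, na.rm = TRUE),
                   ei_sd = stats::sd(per_trial$ei, na.rm = TRUE),
                   th_rate_mean = mean(per_trial$th_rate))
  })
}

#' Dendrite-degeneration sweep
#'
#' As [run_spine_sweep()] but removing `Nd` secondary/subordinate dendrite
#' sections (fraction `Nd/32`) from every MSN.
#'
#' @param depletion dopamine depletion fraction.
#' @param nd_grid dendrite-removal counts (subset of 0..32).
#' @inheritParams run_spine_sweep
#' @return tibble: `nd`, `degeneration_fraction`, `ei_mean`, `ei_sd`,
#'   `th_rate_mean`.
#' @export
run_dendrite_sweep <- function(depletion, nd_grid = seq(0, 32, by = 8),
                               trials = 5, seed = 1L, duration = 2000,
                               config = network_config()) {
  stopifnot(all(nd_grid >= 0 & nd_grid <= 32))
  seeds <- trial_seeds(seed, trials)
  cals <- lapply(seeds, function(s) relay_calibration(config, s, duration))
  purrr::map_dfr(nd_grid, function(nd) {
    cfg <- config
    cfg$dopamine_depletion <- depletion
    cfg$nd <- as.integer(nd)
    per_trial <- purrr::map_dfr(seq_along(seeds), function(i) {
      score_relay(cfg, seeds[i], duration, calibration = cals[[i]])
    })
    tibble::tibble(nd = nd, degeneration_fraction = nd / 32,
                   ei_mean = mean(per_trial$ei, na.rm = TRUE),
                   ei_sd = stats::sd(per_trial$ei, na.rm = TRUE),
                   th_rate_mean = mean(per_trial$th_rate))
  })
}

#' Cortical AC stimulation grid
#'
#' Injects `I_stim = A * sin(2*pi*f*t)` into every cortical cell of a
#' depleted network and reports the five-number summary of EI over trials
#' for each (amplitude, frequency) grid cell. Frequencies are physical Hz
#' (converted internally to the per-ms angular coefficient).
#'
#' @param depletion depletion fraction (0.5 for the published protocol).
#' @param amp_grid stimulus amplitudes (uA/cm2).
#' @param freq_grid stimulus frequencies (Hz).
#' @param trials trials per cell.
#' @param seed base seed.
#' @param duration trial duration (ms).
#' @param config base configuration.
#' @return tibble: `amplitude`, `frequency`, `ei_min`, `ei_q1`,
#'   `ei_median`, `ei_q3`, `ei_max`, `th_rate_mean`.
#' @export
run_cortical_stim_grid <- function(depletion = 0.5, amp_grid = c(1),
                                   freq_grid = c(10), trials = 5,
                                   seed = 1L, duration = 2000,
                                   config = network_config()) {
  seeds <- trial_seeds(seed, trials)
  cals <- lapply(seeds, function(s) relay_calibration(config, s, duration))
  grid <- tidyr::expand_grid(amplitude = amp_grid, frequency = freq_grid)
  purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    a <- grid$amplitude[gi]; f <- grid$frequency[gi]
    omega <- 2 * pi * f / 1000
    cfg <- config
    cfg$dopamine_depletion <- depletion
    eis <- vapply(seq_along(seeds), function(i) {
      net <- build_network(cfg)
      stim <- stimulus("py", make_waveform("sine", amp = a, omega = omega))
      rec <- simulate_network(
        net, sim_spec(duration = duration, seed = seeds[i],
                      stimuli = list(stim)))
      sc <- score_recording(rec, cals[[i]])
      sc$ei
    }, numeric(1))
    fv <- stats::fivenum(eis, na.rm = TRUE)
    tibble::tibble(amplitude = a, frequency = f,
                   ei_min = fv[1], ei_q1 = fv[2], ei_median = fv[3],
                   ei_q3 = fv[4], ei_max = fv[5],
                   ei_mean = mean(eis, na.rm = TRUE))
  })
}
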
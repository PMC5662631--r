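#' Electromagnetic-induction parameters for the cortical neuron
#'
#' Flux-coupling and memconductance constants of the memristive cortical
#' neuron: `phi' = k1*v - k2*phi`, feedback current `k*rho(phi)*(v + Ve)`
#' with `rho(phi) = alpha + 3*beta*phi^2`, and AC field `Ve =
#' a_e*sin(omega*t)`. Defaults are the published operating point
#' (k = 0.001, k1 = 0.1, k2 = 1, alpha = 0.4, beta = 0.01).
#'
#' `omega` is the literal angular coefficient inside `sin(omega*t)` with
#' `t` in ms; pass `2*pi*f/1000` for a physical frequency `f` in Hz.
#'
#' @param k,k1,k2 flux-coupling coefficients.
#' @param alpha,beta memconductance constants (> 0).
#' @param a_e AC field amplitude (mV).
#' @param omega angular coefficient (per ms).
#' @param i_app constant forcing current (uA/cm2).
#' @return list of class `em_params`.
#' @export
em_params <- function(k = 0.001, k1 = 0.1, k2 = 1, alpha = 0.4,
                      beta = 0.01, a_e = 0, omega = 6.27, i_app = 0) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(k = k, k1 = k1, k2 = k2, alpha = alpha, beta = beta,
                 a_e = a_e, omega = omega, i_app = i_app),
            class = "em_params")
}

#' Memconductance
#'
#' `rho(phi) = alpha + 3*beta*phi^2` -- the flux-controlled conductance
#' coupling the magnetic-flux variable back onto the membrane.
#'
#' @param phi magnetic flux (model units); vectorised.
#' @param alpha,beta positive constants.
#' @return conductance value(s).
#' @export
memconductance <- function(phi, alpha = 0.4, beta = 0.01) {
  stopifnot(alpha > 0, beta > 0)
  alpha + 3 * beta * phi^2
}

#' EM cortical neuron right-hand side (reference implementation)
#'
#' The pyramidal cell of [py_rhs()] with channel driving forces evaluated
#' at `v + Ve` (`Ve = a_e*sin(omega*t)`), gate kinetics at `v`, the field
#' term `-a_e*omega*Cm*cos(omega*t)`, the memconductance feedback current
#' and the linear flux equation. With `a_e = 0` and `k = 0` the model
#' reduces exactly to the plain pyramidal cell.
#'
#' @param state named vector `c(v, m, h, n, q, r, p, phi)`.
#' @param params an [em_params()] list.
#' @param t time (ms).
#' @param py [cell_params()] for the pyramidal backbone.
#' @return named derivative vector.
#' @export
em_rhs <- function(state, params = em_params(), t = 0,
                   py = cell_params("py")) {
  validate_state(state)
  v <- state[["v"]]; phi <- state[["phi"]]
  ve <- params$a_e * sin(params$omega * t)
  u <- v + ve
  k <- py_kinetics(v, py$v_t, py$tau_max)
  m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  q <- state[["q"]]; r <- state[["r"]]; p <- state[["p"]]
  i_leak <- py$g_leak * (u - py$e_leak)
  i_na <- py$g_na * m^3 * h * (u - py$e_na)
  i_kd <- py$g_kd * n^4 * (u - py$e_k)
  i_m <- py$g_m * p * (u - py$e_k)
  i_lca <- py$g_lca * q^2 * r * (u - py$e_ca)
  rho <- memconductance(phi, params$alpha, params$beta)
  dv <- (-i_leak - i_na - i_kd - i_m - i_lca -
           params$a_e * params$omega * py$cm * cos(params$omega * t) +
           params$i_app + params$k * rho * u) / py$cm
  c(v = dv,
    m = k$am * (1 - m) - k$bm * m,
    h = k$ah * (1 - h) - k$bh * h,
    n = k$an * (1 - n) - k$bn * n,
    q = k$aq * (1 - q) - k$bq * q,
    r = k$ar * (1 - r) - k$br * r,
    p = (k$p_inf - p) / k$tau_p,
    phi = params$k1 * v - params$k2 * phi)
}

#' Simulate the standalone EM cortical neuron
#'
#' Fixed-step integration (compiled) of the memristive, AC-driven cortical
#' neuron.
#'
#' @param params an [em_params()].
#' @param duration total time (ms).
#' @param dt step (ms).
#' @param record_stride keep every n-th sample.
#' @param v0 initial membrane potential (mV).
#' @return `bg_recording`-like list with `times`, `v`.
#' @export
simulate_em <- function(params = em_params(), duration = 12000, dt = 0.025,
                        record_stride = 10L, v0 = -71) {
  py <- cell_params("py")
  ord_py <- c("cm", "g_leak", "e_leak", "g_na", "e_na", "g_kd", "e_k",
              "g_m", "tau_max", "g_lca", "e_ca", "v_t", "i_app")
  st <- cell_state("py", v = v0)
  state0 <- c(st[["v"]], st[["m"]], st[["h"]], st[["n"]], st[["q"]],
              st[["r"]], st[["p"]], params$k1 * v0 / params$k2)
  out <- sim_em_cpp(unname(unlist(py[ord_py])),
                    c(params$k, params$k1, params$k2, params$alpha,
                      params$beta, params$a_e, params$omega, params$i_app),
                    duration, dt, as.integer(record_stride), state0)
  structure(list(times = out$times, v = out$v, state = out$state,
                 params = params),
            class = "em_recording")
}

#' Classify the discharge mode of a voltage trace
#'
#' Mode labels for the EM cortical neuron: from spike detection and
#' inter-spike-interval statistics after a discarded transient.
#' No spikes and peak-to-peak voltage below `smpo_threshold` is
#' `"quiescent"`; no spikes with larger sub-threshold excursion is
#' `"SMPO"`; unimodal narrow ISI distribution is `"spiking_period1"`;
#' grouped ISIs (clear burst gaps) with a regular per-burst spike count
#' `n` is `"bursting_period_n"`; alternating burst sizes are
#' `"mixed_mode"`; irregular ISIs with high return-map dispersion and no
#' short period are `"chaotic"`.
#'
#' @param trace voltage trace (mV).
#' @param dt sample interval (ms).
#' @param transient discard this initial time (ms), default 2000.
#' @param smpo_threshold peak-to-peak threshold (mV) separating quiescence
#'   from sub-threshold membrane potential oscillation, default 0.5.
#' @param isi_gap burst-delimiting ISI (ms); `NULL` splits widely bimodal
#'   ISI distributions at the geometric mean of their extremes and falls
#'   back to `3 * median(ISI)` otherwise.
#' @return a one-row tibble: `mode`, `n_spikes`, `rate_hz`,
#'   `spikes_per_burst`, `p2p`.
#' @export
classify_mode <- function(trace, dt, transient = 2000,
                          smpo_threshold = 0.5, isi_gap = NULL) {
  n_keep <- length(trace) - round(transient / dt)
  if (n_keep < round(1000 / dt)) {
    stop("trace too short for mode classification (need >= 1 s after transient)")
  }
  v <- trace[(length(trace) - n_keep + 1):length(trace)]
  span <- n_keep * dt
  sp <- detect_spikes(v, dt)
  p2p <- max(v) - min(v)
  base <- tibble::tibble(n_spikes = length(sp),
                         rate_hz = 1000 * length(sp) / span,
                         p2p = p2p)
  if (length(sp) < 2) {
    mode <- if (length(sp) <= 1 && p2p < smpo_threshold) "quiescent"
    else if (length(sp) <= 1) "SMPO" else "spiking_period1"
    return(dplyr::mutate(base, mode = mode,
                         spikes_per_burst = as.numeric(length(sp))))
  }
  isi <- diff(sp)
  cv_isi <- stats::sd(isi) / mean(isi)
  if (cv_isi < 0.15) {
    # unimodal narrow ISI distribution: regular single-spike rhythm
    return(dplyr::mutate(base, mode = "spiking_period1",
                         spikes_per_burst = 1))
  }
  if (is.null(isi_gap)) {
    # widely bimodal ISI distributions split at the geometric mean of the
    # extremes; otherwise fall back to a multiple of the median
    isi_gap <- if (max(isi) / max(min(isi), 1e-9) > 5) {
      sqrt(min(isi) * max(isi))
    } else {
      3 * stats::median(isi)
    }
  }
  burst_id <- cumsum(c(1, diff(sp) > isi_gap))
  counts <- tabulate(burst_id)
  spb <- mean(counts)
  if (max(counts) == 1) {
    mode <- "chaotic"
    return(dplyr::mutate(base, mode = mode, spikes_per_burst = spb))
  }
  # burst structure: judge regularity of per-burst counts (ignore edges)
  core <- counts[c(-1, -length(counts))]
  if (!length(core)) core <- counts
  if (length(unique(core)) == 1) {
    mode <- paste0("bursting_period_", core[1])
  } else if (all(sort(unique(core)) %in% range(core)) &&
             diff(range(core)) <= 2 && length(unique(core)) == 2) {
    mode <- "mixed_mode"
  } else {
    mode <- "chaotic"
  }
  dplyr::mutate(base, mode = mode, spikes_per_burst = spb)
}

#' Sweep the EM cortical neuron over a parameter grid
#'
#' Runs [simulate_em()] for every row of the grid and classifies the
#' discharge mode.
#'
#' @param grid data frame with any of the columns `a_e`, `omega`, `i_app`
#'   (missing columns use the `base` values).
#' @param base an [em_params()] giving fixed parameters.
#' @param duration,dt,transient simulation controls.
#' @return the grid tibble augmented with `mode`, `rate_hz`,
#'   `spikes_per_burst`, `p2p`.
#' @export
em_mode_sweep <- function(grid, base = em_params(), duration = 12000,
                          dt = 0.025, transient = 2000) {
  if (!nrow(grid)) stop("em_mode_sweep: empty grid")
  grid <- tibble::as_tibble(grid)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    p <- base
    for (f in intersect(names(grid), c("a_e", "omega", "i_app"))) {
      p[[f]] <- grid[[f]][i]
    }
    rec <- simulate_em(p, duration = duration, dt = dt)
    cl <- classify_mode(rec$v, dt * 10, transient = transient)
    dplyr::bind_cols(grid[i, ], cl[, c("mode", "rate_hz",
                                       "spikes_per_burst", "p2p")])
  })
  res
}
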
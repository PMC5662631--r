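# Assembly of the compiled-engine configuration and the user-facing
# simulate() front end.

pop_order <- c("th", "stn", "gpe", "gpi", "py", "da", "d1", "d2")
type_code <- c(th = 0L, stn = 1L, gpe = 2L, gpi = 3L, py = 4L, da = 5L,
               d1 = 6L, d2 = 6L)

#' Simulation specification
#'
#' @param duration total simulated time (ms).
#' @param dt integration step (ms), default 0.025.
#' @param seed integer seed controlling the initial-condition jitter that
#'   decorrelates otherwise identical cells (the engine itself is
#'   deterministic).
#' @param record_stride store every `record_stride`-th sample (default 10,
#'   i.e. 0.25 ms resolution at the default dt).
#' @param record character vector of populations to record (voltage
#'   traces); `"all"` records every soma.
#' @param stimuli list of stimulus entries as built by [make_waveform()]
#'   combined with a target, see [stimulus()].
#' @return list of class `bg_sim_spec`.
#' @export
sim_spec <- function(duration = 2000, dt = 0.025, seed = 1L,
                     record_stride = 10L,
                     record = c("th", "gpi", "gpe", "stn", "d1", "d2"),
                     stimuli = list()) {
  stopifnot(dt > 0, duration >= dt)
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 record_stride = as.integer(record_stride),
                 record = record, stimuli = stimuli),
            class = "bg_sim_spec")
}

#' Stimulus waveform constructor
#'
#' @param kind `"constant"` or `"sine"`; a sine stimulus is
#'   `A * sin(omega * t)` with `t` in ms.
#' @param amp amplitude (uA/cm2 for density targets).
#' @param omega angular coefficient for `"sine"` (per ms).
#' @param t_on,t_off activation window (ms).
#' @return function of time `t` (ms) evaluating the waveform, with the
#'   parameters attached as attributes.
#' @export
make_waveform <- function(kind = c("constant", "sine"), amp = 0,
                          omega = 0, t_on = 0, t_off = Inf) {
  kind <- match.arg(kind)
  f <- switch(kind,
    constant = function(t) ifelse(t >= t_on & t <= t_off, amp, 0),
    sine = function(t) ifelse(t >= t_on & t <= t_off,
                              amp * sin(omega * t), 0))
  structure(f, kind = kind, amp = amp, omega = omega,
            t_on = t_on, t_off = t_off, class = c("bg_waveform", "function"))
}

#' Attach a waveform to a target population (or single cell)
#'
#' @param population target population name; MSNs accept an optional
#'   `comp` compartment id (default soma).
#' @param waveform a [make_waveform()] object.
#' @param id cell index within the population, or `NULL` for all cells.
#' @param comp compartment id for MSN targets (default 1, the soma).
#' @return stimulus entry for [sim_spec()].
#' @export
stimulus <- function(population, waveform, id = NULL, comp = 1L) {
  stopifnot(inherits(waveform, "bg_waveform"))
  list(population = population, id = id, comp = as.integer(comp),
       waveform = waveform)
}

# ---- engine configuration assembly -----------------------------------

build_engine_config <- function(net, spec) {
  cfg <- net$config
  chan <- msn_channel_table()
  mp <- msn_params()
  slots <- msn_state_slots(chan)
  MAXS <- 24L

  sizes <- c(th = cfg$n_th, stn = cfg$n_stn, gpe = cfg$n_gpe,
             gpi = cfg$n_gpi, py = cfg$n_py, da = cfg$n_da,
             d1 = cfg$n_d1, d2 = cfg$n_d2)

  unit_type <- integer(); unit_cell <- integer(); unit_bias <- numeric()
  unit_is_soma <- integer(); unit_nstate <- integer()
  cell_pop <- character(); cell_id <- integer(); cell_soma <- integer()
  state_rows <- list()
  # map: population/id -> cell index (0-based); MSN comp -> unit index
  cell_key <- character()
  unit_key <- character()
  coup_a <- integer(); coup_b <- integer()
  coup_ca <- numeric(); coup_cb <- numeric()

  rng_jitter <- local_rng(spec$seed + 999L)
  jitters <- NULL

  nu <- 0L; ncell <- 0L
  single_nstate <- c(th = 3L, stn = 5L, gpe = 5L, gpi = 5L, py = 7L,
                     da = 11L)
  for (pop in pop_order) {
    n <- sizes[[pop]]
    for (i in seq_len(n)) {
      ncell <- ncell + 1L
      cell_pop <- c(cell_pop, pop); cell_id <- c(cell_id, i)
      cell_key <- c(cell_key, paste0(pop, "_", i))
      if (pop %in% c("d1", "d2")) {
        m <- net$msn[[paste0(pop, "_", i)]]
        comps <- m$comps
        first_unit <- nu
        local_units <- stats::setNames(nu + seq_len(nrow(comps)) - 1L,
                                       comps$id)
        for (r in seq_len(nrow(comps))) {
          nu <- nu + 1L
          unit_type <- c(unit_type, 6L)
          unit_cell <- c(unit_cell, ncell - 1L)
          unit_bias <- c(unit_bias,
                         if (comps$level[r] == "soma") cfg$bias$i_appmsn
                         else 0)
          unit_is_soma <- c(unit_is_soma,
                            as.integer(comps$level[r] == "soma"))
          unit_nstate <- c(unit_nstate, length(slots))
          unit_key <- c(unit_key, paste0(pop, "_", i, "_c", comps$id[r]))
          st <- msn_init_state(comps$v[r], chan = chan)
          state_rows[[nu]] <- c(st, numeric(MAXS - length(st)))
        }
        cell_soma <- c(cell_soma, first_unit)  # soma is the first row
        cp <- msn_couplings(m, mp)
        coup_a <- c(coup_a, unname(local_units[as.character(cp$parent)]))
        coup_b <- c(coup_b, unname(local_units[as.character(cp$child)]))
        coup_ca <- c(coup_ca, cp$coef_parent)
        coup_cb <- c(coup_cb, cp$coef_child)
      } else {
        nu <- nu + 1L
        unit_type <- c(unit_type, type_code[[pop]])
        unit_cell <- c(unit_cell, ncell - 1L)
        unit_bias <- c(unit_bias, 0)
        unit_is_soma <- c(unit_is_soma, 0L)
        unit_nstate <- c(unit_nstate, single_nstate[[pop]])
        unit_key <- c(unit_key, paste0(pop, "_", i))
        jit <- (sample_seeded(seq_len(2001), rng_jitter)[1] - 1001) / 1000
        st <- cell_state(pop, v = switch(pop, th = -68, stn = -62,
                                         gpe = -66, gpi = -66, py = -71,
                                         da = -58) + 3 * jit)
        state_rows[[nu]] <- c(st, numeric(MAXS - length(st)))
        cell_soma <- c(cell_soma, nu - 1L)
      }
    }
  }
  state0 <- do.call(rbind, state_rows)

  # parameter vectors with config biases folded in
  p_th <- cell_params("th", i_app = cfg$bias$i_appth)
  p_stn <- cell_params("stn", i_app = cfg$bias$i_appstn)
  p_gpe <- cell_params("gpe", i_app = cfg$bias$i_appgpe)
  p_gpi <- cell_params("gpi", i_app = cfg$bias$i_appgpi)
  p_py <- cell_params("py", i_app = cfg$bias$i_appcor)
  p_da <- cell_params("da", i_app = cfg$bias$i_appda)

  flat <- function(p, ord) unname(unlist(p[ord]))
  ord_th <- c("cm", "g_l", "e_l", "g_na", "e_na", "g_k", "e_k", "g_t",
              "e_t", "i_app")
  ord_stn <- c("cm", "g_l", "e_l", "g_na", "e_na", "g_k", "e_k", "g_t",
               "g_ca", "e_ca", "g_ahp", "k1", "k_ca", "eps", "phi_h",
               "phi_n", "phi_r", "i_app")
  ord_gp <- c(ord_stn[1:14], "phi_h", "phi_n", "phi_r", "tau_r", "i_app")
  ord_py <- c("cm", "g_leak", "e_leak", "g_na", "e_na", "g_kd", "e_k",
              "g_m", "tau_max", "g_lca", "e_ca", "v_t", "i_app")
  ord_da <- c("cm", "g_na", "e_na", "g_kdr", "e_k", "g_a", "g_sk", "k_sk",
              "g_cat", "g_can", "g_cal", "e_ca", "i_napump", "k_capump",
              "g_lna", "e_lna", "g_lk", "g_lca", "f_ca", "tau_ca", "i_app")

  # synapse classes
  cls_names <- c("ampa", "nmda", "gaba", "da_exc", "da_inh")
  syn_cls <- t(vapply(cls_names, function(k) {
    p <- synapse_params(k)
    c(p$tau_on, p$tau_off, p$e_syn, p$g_max)
  }, numeric(4)))

  # edges
  wiring <- net$wiring
  pre_cell <- match(paste0(wiring$pre_pop, "_", wiring$pre_id), cell_key) - 1L
  post_unit <- ifelse(
    is.na(wiring$post_comp),
    match(paste0(wiring$post_pop, "_", wiring$post_id), unit_key),
    match(paste0(wiring$post_pop, "_", wiring$post_id, "_c",
                 wiring$post_comp), unit_key)) - 1L
  if (anyNA(pre_cell) || anyNA(post_unit)) {
    stop("internal wiring inconsistency: unresolved endpoint")
  }
  e_cls <- match(wiring$class, cls_names) - 1L

  # stimuli -> engine entries
  stims <- list()
  for (s in spec$stimuli) {
    wf <- s$waveform
    ids <- if (is.null(s$id)) seq_len(sizes[[s$population]]) else s$id
    for (i in ids) {
      ukey <- if (s$population %in% c("d1", "d2")) {
        paste0(s$population, "_", i, "_c", s$comp)
      } else paste0(s$population, "_", i)
      u <- match(ukey, unit_key) - 1L
      if (is.na(u)) stop("stimulus target not found: ", ukey)
      stims[[length(stims) + 1L]] <- list(
        unit = as.integer(u),
        kind = if (attr(wf, "kind") == "constant") 0L else 1L,
        amp = attr(wf, "amp"), omega = attr(wf, "omega"),
        t0 = attr(wf, "t_on"),
        t1 = min(attr(wf, "t_off"), spec$duration + 1))
    }
  }

  # probes: soma units of recorded populations
  rec_pops <- if (identical(spec$record, "all")) pop_order else spec$record
  probe_units <- integer(); probe_names <- character()
  for (ci in seq_len(ncell)) {
    if (cell_pop[ci] %in% rec_pops) {
      probe_units <- c(probe_units, cell_soma[ci])
      probe_names <- c(probe_names, paste0(cell_pop[ci], "_", cell_id[ci]))
    }
  }

  list(
    dt = spec$dt,
    n_steps = as.integer(round(spec$duration / spec$dt)),
    record_stride = spec$record_stride,
    spike_threshold = -20, refractory = 2,
    unit_type = unit_type, unit_cell = unit_cell, unit_bias = unit_bias,
    unit_is_soma = unit_is_soma, unit_nstate = unit_nstate,
    cell_soma_unit = cell_soma,
    state0 = state0,
    p_th = flat(p_th, ord_th), p_stn = flat(p_stn, ord_stn),
    p_gpe = flat(p_gpe, ord_gp), p_gpi = flat(p_gpi, ord_gp),
    p_py = flat(p_py, ord_py), p_da = flat(p_da, ord_da),
    msn_channels = as.matrix(chan[, -1]),
    msn_cm = mp$cm, msn_ca_f = mp$ca_f, msn_ca_tau = mp$ca_tau,
    msn_e_ca = mp$e_ca,
    msn_ca_slot = length(slots) - 1L,
    coup_a = coup_a, coup_b = coup_b, coup_ca = coup_ca, coup_cb = coup_cb,
    syn_classes = syn_cls,
    edge_pre = pre_cell, edge_post = post_unit, edge_cls = e_cls,
    edge_w = wiring$weight,
    stims = stims,
    probes = probe_units,
    probe_names = probe_names,
    cell_pop = cell_pop, cell_id = cell_id
  )
}

#' Integrate a network
#'
#' Fixed-step integration of the full network state: all cell compartments,
#' synapse states and stimulus waveforms advance at `dt` (default 0.025
#' ms); spikes are detected online (upward crossing of -20 mV, 2 ms
#' lockout). Bit-reproducible for a fixed spec and seed.
#'
#' @param net a [build_network()] object.
#' @param spec a [sim_spec()].
#' @return object of class `bg_recording`: `times` (ms), `traces` (matrix,
#'   one row per probe), `spikes` tibble (`population`, `id`, `time`), and
#'   the spec/config echo.
#' @examples
#' \donttest{
#' net <- build_network(network_config())
#' rec <- simulate_network(net, sim_spec(duration = 200))
#' head(tidy(rec))
#' }
#' @export
simulate_network <- function(net, spec = sim_spec()) {
  stopifnot(inherits(net, "bg_network"), inherits(spec, "bg_sim_spec"))
  ecfg <- build_engine_config(net, spec)
  out <- sim_network_cpp(ecfg)
  traces <- out$traces
  rownames(traces) <- ecfg$probe_names
  sp <- out$spikes
  spikes <- purrr::map_dfr(seq_along(sp), function(ci) {
    if (!length(sp[[ci]])) return(NULL)
    tibble::tibble(population = ecfg$cell_pop[ci], id = ecfg$cell_id[ci],
                   time = sp[[ci]])
  })
  if (!nrow(spikes)) {
    spikes <- tibble::tibble(population = character(), id = integer(),
                             time = numeric())
  }
  structure(
    list(times = out$times, traces = traces, spikes = spikes,
         spec = spec, config = net$config),
    class = "bg_recording"
  )
}

#' @export
print.bg_recording <- function(x, ...) {
  cat(sprintf("<bg_recording> %.0f ms, dt %.3f ms, %d probes, %d spikes\n",
              max(x$times), x$spec$dt, nrow(x$traces), nrow(x$spikes)))
  invisible(x)
}

#' Tidy a recording into a long tibble
#'
#' @param x a `bg_recording`.
#' @param ... unused.
#' @return tibble `time`, `probe`, `population`, `id`, `v`.
#' @export
tidy.bg_recording <- function(x, ...) {
  probes <- rownames(x$traces)
  purrr::map_dfr(seq_along(probes), function(p) {
    tibble::tibble(
      time = x$times,
      probe = probes[p],
      population = sub("_[0-9]+$", "", probes[p]),
      id = as.integer(sub(".*_", "", probes[p])),
      v = x$traces[p, ])
  })
}

#' Per-population summary of a recording
#'
#' @param x a `bg_recording`.
#' @param t_start discard this initial transient (ms) for rates.
#' @param ... unused.
#' @return tibble `population`, `n_cells`, `mean_rate_hz`,
#'   `mean_spikes_per_burst`.
#' @export
glance.bg_recording <- function(x, t_start = 500, ...) {
  dur <- max(x$times)
  pops <- unique(c(x$spikes$population,
                   sub("_[0-9]+$", "", rownames(x$traces))))
  purrr::map_dfr(pops, function(p) {
    n_cells <- length(unique(x$spikes$id[x$spikes$population == p]))
    sp <- x$spikes[x$spikes$population == p & x$spikes$time >= t_start, ]
    per_cell <- split(sp$time, sp$id)
    rates <- vapply(per_cell, mean_firing_rate,
                    window = c(t_start, dur), numeric(1))
    spb <- vapply(per_cell, spikes_per_burst, numeric(1))
    tibble::tibble(
      population = p,
      n_cells = max(n_cells, length(grep(paste0("^", p, "_"),
                                         rownames(x$traces)))),
      mean_rate_hz = if (length(rates)) mean(rates) else 0,
      mean_spikes_per_burst = if (length(spb)) mean(spb) else 0)
  })
}

#' Extract one probe trace
#'
#' @param rec a `bg_recording`.
#' @param probe probe name, e.g. `"th_1"`.
#' @return numeric voltage vector.
#' @export
get_trace <- function(rec, probe) {
  if (!probe %in% rownames(rec$traces)) {
    stop("probe not recorded: ", probe)
  }
  rec$traces[probe, ]
}

#' Spike times for one cell
#' @param rec a `bg_recording`.
#' @param population population name.
#' @param id cell index.
#' @return numeric spike times (ms).
#' @export
get_spikes <- function(rec, population, id = 1) {
  rec$spikes$time[rec$spikes$population == population & rec$spikes$id == id]
}

#' Simulate a single cell with the fixed-step engine
#'
#' Integrates one isolated cell (no synapses) with an optional stimulus
#' waveform, using exactly the same compiled stepping code as the network
#' engine. For `type = "msn"` a full intact MSN morphology is integrated
#' and the soma recorded.
#'
#' @param type one of `"th"`, `"stn"`, `"gpe"`, `"gpi"`, `"py"`, `"da"`,
#'   `"msn"`.
#' @param duration total time (ms).
#' @param dt step (ms).
#' @param i_ext a [make_waveform()] object, or a constant (uA/cm2,
#'   inward positive).
#' @param params [cell_params()] overrides for the cell (ignored for MSN).
#' @param v0 initial membrane potential (mV); default the type's rest.
#' @param record_stride keep every n-th sample.
#' @return list with `times`, `v` (soma trace) and `spikes` (ms).
#' @export
simulate_cell <- function(type, duration = 1000, dt = 0.025, i_ext = 0,
                          params = NULL, v0 = NULL, record_stride = 1L) {
  MAXS <- 24L
  chan <- msn_channel_table()
  mp <- msn_params()
  slots <- msn_state_slots(chan)
  if (inherits(i_ext, "bg_waveform")) {
    i_ext <- list(i_ext)
  } else if (!is.list(i_ext)) {
    i_ext <- list(make_waveform("constant", amp = i_ext))
  }
  stopifnot(all(vapply(i_ext, inherits, logical(1), "bg_waveform")))
  flat <- function(p, ord) unname(unlist(p[ord]))
  ords <- list(
    th = c("cm", "g_l", "e_l", "g_na", "e_na", "g_k", "e_k", "g_t", "e_t",
           "i_app"),
    stn = c("cm", "g_l", "e_l", "g_na", "e_na", "g_k", "e_k", "g_t",
            "g_ca", "e_ca", "g_ahp", "k1", "k_ca", "eps", "phi_h", "phi_n",
            "phi_r", "i_app"),
    py = c("cm", "g_leak", "e_leak", "g_na", "e_na", "g_kd", "e_k", "g_m",
           "tau_max", "g_lca", "e_ca", "v_t", "i_app"),
    da = c("cm", "g_na", "e_na", "g_kdr", "e_k", "g_a", "g_sk", "k_sk",
           "g_cat", "g_can", "g_cal", "e_ca", "i_napump", "k_capump",
           "g_lna", "e_lna", "g_lk", "g_lca", "f_ca", "tau_ca", "i_app"))
  ords$gpe <- ords$gpi <- c(ords$stn[1:14], "phi_h", "phi_n", "phi_r",
                            "tau_r", "i_app")
  pvec <- function(ty) {
    p <- if (!is.null(params) && ty == type) params else cell_params(
      if (ty == "msn") "th" else ty)
    flat(p, ords[[if (ty == "msn") "th" else ty]])
  }
  if (type == "msn") {
    m <- build_morphology("d1")
    ncomp <- nrow(m$comps)
    unit_type <- rep(6L, ncomp)
    unit_is_soma <- as.integer(m$comps$level == "soma")
    unit_nstate <- rep(length(slots), ncomp)
    state0 <- t(vapply(m$comps$v, function(v) {
      st <- msn_init_state(v, chan = chan)
      c(st, numeric(MAXS - length(st)))
    }, numeric(MAXS)))
    cp <- msn_couplings(m, mp)
    lu <- stats::setNames(seq_len(ncomp) - 1L, m$comps$id)
    coup_a <- unname(lu[as.character(cp$parent)])
    coup_b <- unname(lu[as.character(cp$child)])
    coup_ca <- cp$coef_parent; coup_cb <- cp$coef_child
    soma_unit <- 0L
  } else {
    st <- if (is.null(v0)) cell_state(type) else cell_state(type, v = v0)
    if (!is.null(params)) {
      # params may shift the rest point; state still initialised at v
      st <- cell_state(type, v = if (is.null(v0)) st[["v"]] else v0)
    }
    state0 <- matrix(c(st, numeric(MAXS - length(st))), nrow = 1)
    unit_type <- type_code[[type]]
    unit_is_soma <- 0L
    unit_nstate <- length(st)
    coup_a <- coup_b <- integer()
    coup_ca <- coup_cb <- numeric()
    soma_unit <- 0L
  }
  p_by <- list(th = "th", stn = "stn", gpe = "gpe", gpi = "gpi",
               py = "py", da = "da", msn = "th")
  pl <- list()
  for (ty in c("th", "stn", "gpe", "gpi", "py", "da")) {
    p <- if (!is.null(params) && ty == type) params else cell_params(ty)
    pl[[ty]] <- flat(p, ords[[ty]])
  }
  cls_names <- c("ampa", "nmda", "gaba", "da_exc", "da_inh")
  syn_cls <- t(vapply(cls_names, function(k) {
    p <- synapse_params(k); c(p$tau_on, p$tau_off, p$e_syn, p$g_max)
  }, numeric(4)))
  ecfg <- list(
    dt = dt, n_steps = as.integer(round(duration / dt)),
    record_stride = as.integer(record_stride),
    spike_threshold = -20, refractory = 2,
    unit_type = as.integer(unit_type),
    unit_cell = rep(0L, length(unit_type)),
    unit_bias = rep(0, length(unit_type)),
    unit_is_soma = as.integer(unit_is_soma),
    unit_nstate = as.integer(unit_nstate),
    cell_soma_unit = soma_unit,
    state0 = state0,
    p_th = pl$th, p_stn = pl$stn, p_gpe = pl$gpe, p_gpi = pl$gpi,
    p_py = pl$py, p_da = pl$da,
    msn_channels = as.matrix(chan[, -1]),
    msn_cm = mp$cm, msn_ca_f = mp$ca_f, msn_ca_tau = mp$ca_tau,
    msn_e_ca = mp$e_ca, msn_ca_slot = length(slots) - 1L,
    coup_a = coup_a, coup_b = coup_b, coup_ca = coup_ca, coup_cb = coup_cb,
    syn_classes = syn_cls,
    edge_pre = integer(), edge_post = integer(), edge_cls = integer(),
    edge_w = numeric(),
    stims = lapply(i_ext, function(wf) {
      list(unit = 0L,
           kind = if (attr(wf, "kind") == "constant") 0L else 1L,
           amp = attr(wf, "amp"), omega = attr(wf, "omega"),
           t0 = attr(wf, "t_on"),
           t1 = min(attr(wf, "t_off"), duration + 1))
    }),
    probes = soma_unit
  )
  out <- sim_network_cpp(ecfg)
  list(times = out$times, v = out$traces[1, ], spikes = out$spikes[[1]],
       state = out$state[1, seq_len(ecfg$unit_nstate[1])])
}
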
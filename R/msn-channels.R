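# Medium spiny neuron channel inventory.
#
# The MSN carries 14 intrinsic channel families plus leak: fast and
# persistent Na; fast/slow A-type, persistent (KRP, soma only), inwardly
# rectifying (KIR), and the small (SK) and large (BK) calcium-activated K
# channels; and six Ca channel types (L1.2, L1.3, N, Q, R, T). Kinetics are
# Boltzmann steady states with bell-shaped (or constant) time constants:
# tau(v) = tau0 + tau1 / (exp((v - tv)/ka) + exp(-(v - tv)/kb)).
# Dendritic compartments carry the same channels except KRP (g_dend = 0).
#
# ca_mode: 0 voltage-gated; 1 voltage gate multiplied by a Hill-2 calcium
# factor (BK); 2 gate relaxing toward Hill-2 of calcium (SK); 3 ohmic leak.

#' MSN channel parameter table
#'
#' One row per channel family of the medium spiny neuron model (plus leak).
#' Conductance densities are mS/cm2 (`g_soma` somatic, `g_dend` dendritic),
#' reversal potentials mV. The same table drives both the R reference
#' dynamics and the compiled engine.
#'
#' @return a tibble with one row per channel.
#' @export
msn_channel_table <- function() {
  tribble_cols <- c("channel", "g_soma", "g_dend", "e_rev", "p_exp", "has_h",
    "ca_mode", "m_vh", "m_k", "m_tau0", "m_tau1", "m_tv", "m_ka", "m_kb",
    "h_vh", "h_k", "h_tau0", "h_tau1", "h_tv", "h_ka", "h_kb", "ca_kd")
  rows <- list(
    #        g_s    g_d    E    p  h  cam  m_vh   m_k  t0   t1   tv   ka  kb   h_vh   h_k  ht0  ht1  htv  hka hkb  kd
    list("leak", 0.075, 0.075, -75, 0, 0, 3, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("naf", 400, 10, 50, 3, 1, 0, -28, 7, 0.05, 0.2, -30, 12, 12, -50, -7, 0.3, 6, -45, 10, 10, 0),
    list("nap", 0.04, 0.01, 50, 1, 0, 0, -52.6, 4.6, 3, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("kaf", 12, 2, -90, 2, 1, 0, -15, 12, 0.5, 1, -30, 15, 15, -58, -8, 15, 0, 0, 1, 1, 0),
    list("kas", 2, 0.5, -90, 2, 1, 0, -25, 14, 8, 0, 0, 1, 1, -50, -15, 250, 0, 0, 1, 1, 0),
    list("kir", 0.2, 0.2, -90, 1, 0, 0, -82, -9, 2, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("krp", 5, 0, -90, 1, 0, 0, -15, 12, 15, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("bk", 10, 0.5, -90, 1, 0, 1, -20, 10, 1, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0.6),
    list("sk", 1.5, 0.2, -90, 1, 0, 2, 0, 1, 8, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0.35),
    list("cal12", 0.15, 0.03, 100, 2, 0, 0, -8.9, 6.7, 1.5, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("cal13", 0.12, 0.03, 100, 2, 0, 0, -33, 6.7, 1.5, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("can", 0.15, 0.02, 100, 2, 1, 0, -8.7, 7.4, 1, 0, 0, 1, 1, -60, -10, 70, 0, 0, 1, 1, 0),
    list("caq", 0.1, 0.01, 100, 2, 0, 0, -9, 6.6, 1.5, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1, 1, 0),
    list("car", 0.1, 0.02, 100, 3, 1, 0, -10.3, 6.6, 1.5, 0, 0, 1, 1, -33.3, -17, 20, 0, 0, 1, 1, 0),
    list("cat", 0.05, 0.05, 100, 3, 1, 0, -51.7, 6.5, 2, 0, 0, 1, 1, -80, -6.4, 30, 0, 0, 1, 1, 0)
  )
  df <- purrr::map_dfr(rows, function(r) {
    names(r) <- tribble_cols
    tibble::as_tibble(r)
  })
  df
}

#' Global MSN model constants
#'
#' Membrane capacitance, calcium pool dynamics, calcium reversal, axial
#' resistivity and per-level compartment geometry of the stylized MSN.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
msn_params <- function(...) {
  p <- list(
    cm = 1,            # uF/cm2
    ca_f = 0.01,       # uM per (uA/cm2 * ms) calcium influx scaling
    ca_tau = 40,       # ms, pooled calcium clearance
    e_ca = 100,        # mV (ohmic approximation)
    ra = 100,          # Ohm cm axial resistivity
    soma_diam = 16,    # um
    primary_len = 40, primary_diam = 1.5,
    secondary_len = 28, secondary_diam = 1.1,
    subordinate_len = 40, subordinate_diam = 0.7
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown MSN parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

# state slot layout for one MSN compartment, matching the engine:
# v, then one slot per dynamic gate in table order (m before h), ca last.
msn_state_slots <- function(chan = msn_channel_table()) {
  slots <- c("v")
  for (i in seq_len(nrow(chan))) {
    cm <- chan$ca_mode[i]
    if (cm %in% c(0, 1, 2)) slots <- c(slots, paste0(chan$channel[i], "_m"))
    if (chan$has_h[i] == 1) slots <- c(slots, paste0(chan$channel[i], "_h"))
  }
  c(slots, "ca")
}

msn_tau <- function(v, t0, t1, tv, ka, kb) {
  if (t1 == 0) return(rep(t0, length(v)))
  t0 + t1 / (exp((v - tv) / ka) + exp(-(v - tv) / kb))
}

# steady-state initialisation of one compartment at potential v
msn_init_state <- function(v, ca = 0.01, chan = msn_channel_table()) {
  slots <- msn_state_slots(chan)
  st <- stats::setNames(numeric(length(slots)), slots)
  st["v"] <- v
  st["ca"] <- ca
  for (i in seq_len(nrow(chan))) {
    cm <- chan$ca_mode[i]
    nm <- chan$channel[i]
    if (cm %in% c(0, 1)) {
      st[paste0(nm, "_m")] <- sigmoid(v, chan$m_vh[i], chan$m_k[i])
    } else if (cm == 2) {
      st[paste0(nm, "_m")] <- ca^2 / (ca^2 + chan$ca_kd[i]^2)
    }
    if (chan$has_h[i] == 1) {
      st[paste0(nm, "_h")] <- sigmoid(v, chan$h_vh[i], chan$h_k[i])
    }
  }
  st
}

# total ionic current density (uA/cm2, outward positive) for one MSN
# compartment given its state; reference implementation mirrored in C++
msn_ionic_current <- function(st, is_soma, chan = msn_channel_table(),
                              params = msn_params()) {
  v <- st[["v"]]; ca <- st[["ca"]]
  itot <- 0; ica <- 0
  for (i in seq_len(nrow(chan))) {
    g <- if (is_soma) chan$g_soma[i] else chan$g_dend[i]
    if (g == 0) next
    cm <- chan$ca_mode[i]
    nm <- chan$channel[i]
    act <- if (cm == 3) {
      1
    } else if (cm == 2) {
      st[[paste0(nm, "_m")]]
    } else {
      a <- st[[paste0(nm, "_m")]]^chan$p_exp[i]
      if (chan$has_h[i] == 1) a <- a * st[[paste0(nm, "_h")]]
      if (cm == 1) a <- a * ca^2 / (ca^2 + chan$ca_kd[i]^2)
      a
    }
    icur <- g * act * (v - chan$e_rev[i])
    itot <- itot + icur
    if (abs(chan$e_rev[i] - params$e_ca) < 1e-9) ica <- ica + icur
  }
  list(total = itot, ca = ica)
}

#' MSN somatic current-balance right-hand side
#'
#' Reference dynamics for the MSN soma (or any compartment via `comp`):
#' the 14-channel ionic current, the Rall-cable compartment interchange
#' current and the synaptic terms. Used by the oracle tests; network
#' simulations run the same equations in the compiled engine.
#'
#' @param morph an [msn_morphology()] object carrying a `v` column (and
#'   optionally full state in `attr(morph, "state")`).
#' @param i_syn synaptic current onto the compartment (uA/cm2, outward
#'   positive).
#' @param params [msn_params()] list.
#' @param comp compartment id (default the soma).
#' @param state optional full state vector for the compartment (named as
#'   `msn_state_slots()`); defaults to steady state at the compartment's `v`.
#' @param i_ext external injected current (uA/cm2, inward positive).
#' @return list with `dv` (mV/ms) and the ionic/coupling current split.
#' @export
msn_soma_rhs <- function(morph, i_syn = 0, params = msn_params(),
                         comp = 1L, state = NULL, i_ext = 0) {
  comps <- morph$comps
  row <- which(comps$id == comp)
  if (!length(row)) stop("compartment ", comp, " not in morphology")
  if (is.null(state)) state <- msn_init_state(comps$v[row])
  ion <- msn_ionic_current(state, comps$level[row] == "soma")
  icoup <- cable_coupling_current(morph, comp, params = params)
  dv <- (-ion$total + icoup + i_ext - i_syn) / params$cm
  list(dv = dv, i_ion = ion$total, i_couple = icoup)
}
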
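#' Synapse kinetic parameters
#'
#' Two-state (dual-exponential, Exp2Syn-style) synapse classes. Rise/decay
#' constants: AMPA and NMDA from cerebellar/cortical glutamatergic kinetics
#' (NMDA slow, no magnesium-block term -- the conductance is voltage
#' independent by construction); GABA-A from neocortical pyramidal data.
#' Reversals: 0 mV for AMPA/NMDA, -80 mV for GABA. The dopaminergic
#' "synapse" classes use much slower kinetics (volume transmission):
#' excitatory
#' onto D1 (E = 0), inhibitory-shunting onto D2 (E = -85, the MSN down-state
#' potential, so the modulation divides cortical EPSPs without triggering
#' low-threshold rebound).
#'
#' @param kind one of `"ampa"`, `"nmda"`, `"gaba"`, `"da_exc"`, `"da_inh"`.
#' @param ... named overrides (`tau_on`, `tau_off`, `e_syn`, `g_max`).
#' @return list of class `synapse_params`.
#' @export
synapse_params <- function(kind = c("ampa", "nmda", "gaba", "da_exc",
                                    "da_inh"), ...) {
  kind <- match.arg(kind)
  p <- switch(kind,
    ampa = list(tau_on = 0.5, tau_off = 2.5, e_syn = 0, g_max = 1),
    nmda = list(tau_on = 2, tau_off = 100, e_syn = 0, g_max = 1),
    gaba = list(tau_on = 0.5, tau_off = 6, e_syn = -80, g_max = 1),
    da_exc = list(tau_on = 5, tau_off = 200, e_syn = 0, g_max = 1),
    da_inh = list(tau_on = 5, tau_off = 200, e_syn = -85, g_max = 1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown synapse parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (!(p$tau_off > p$tau_on && p$tau_on > 0)) {
    stop("synapse time constants must satisfy tau_off > tau_on > 0")
  }
  structure(c(p, list(kind = kind)), class = "synapse_params")
}

#' New (zero) synapse state
#' @return named vector `c(m = 0, h = 0)`.
#' @export
synapse_state <- function() c(m = 0, h = 0)

#' Instantaneous synaptic current
#'
#' `I_syn = g_max * (h - m) * (v_post - e_syn)` (outward positive).
#'
#' @param state synapse state `c(m, h)`.
#' @param params [synapse_params()].
#' @param v_post postsynaptic membrane potential (mV).
#' @return current in the conductance's density units.
#' @export
synapse_current <- function(state, params, v_post) {
  params$g_max * (state[["h"]] - state[["m"]]) * (v_post - params$e_syn)
}

#' Advance a synapse state by `dt` (closed form)
#'
#' Both state variables relax exponentially toward zero with their own time
#' constants: `m(t+dt) = m(t) exp(-dt/tau_on)` and likewise for `h`.
#'
#' @param state synapse state.
#' @param params [synapse_params()].
#' @param dt time step (ms), > 0.
#' @return updated state.
#' @export
advance_synapse <- function(state, params, dt) {
  stopifnot(dt > 0)
  c(m = state[["m"]] * exp(-dt / params$tau_on),
    h = state[["h"]] * exp(-dt / params$tau_off))
}

#' Dual-exponential peak normalization factor
#'
#' The increment applied to both state variables on a presynaptic spike so
#' that a unitary event peaks at `h - m = 1`. The peak occurs at
#' `t* = ln(tau_off/tau_on) * tau_on*tau_off / (tau_off - tau_on)`.
#'
#' @param params [synapse_params()].
#' @return scalar normalization factor.
#' @export
synapse_norm_factor <- function(params) {
  t_on <- params$tau_on; t_off <- params$tau_off
  t_star <- log(t_off / t_on) * t_on * t_off / (t_off - t_on)
  1 / (exp(-t_star / t_off) - exp(-t_star / t_on))
}

#' Register a presynaptic spike on a synapse
#'
#' Increments `m` and `h` by the peak-normalizing factor (or an explicit
#' value); responses to multiple events sum linearly.
#'
#' @param state synapse state.
#' @param normalization increment; defaults to [synapse_norm_factor()] of
#'   `params`.
#' @param params [synapse_params()]; needed when `normalization` is NULL.
#' @return updated state.
#' @export
on_presynaptic_spike <- function(state, normalization = NULL, params = NULL) {
  if (is.null(normalization)) {
    if (is.null(params)) stop("provide either normalization or params")
    normalization <- synapse_norm_factor(params)
  }
  c(m = state[["m"]] + normalization, h = state[["h"]] + normalization)
}

#' Weighted synaptic current for a connection
#'
#' `I_{a->b} = g_{a->b} * I_syn`.
#'
#' @param g_edge connection weight (>= 0).
#' @param i_syn unitary synaptic current.
#' @return scaled current.
#' @export
weighted_current <- function(g_edge, i_syn) {
  if (any(g_edge < 0)) stop("connection weights must be non-negative")
  g_edge * i_syn
}
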
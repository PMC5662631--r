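#' Default biophysical parameters for a cell type
#'
#' Returns the full named parameter list for one of the six single-compartment
#' cell types of the circuit: thalamocortical relay (`"th"`), subthalamic
#' (`"stn"`), external/internal pallidal (`"gpe"`, `"gpi"`), cortical
#' regular-spiking pyramidal (`"py"`) and dopaminergic (`"da"`). Units follow
#' the usual surface-density convention: capacitance in uF/cm2, conductances
#' in mS/cm2, reversal potentials in mV, currents in uA/cm2, time in ms.
#'
#' TH/STN/GPe/GPi kinetics follow the Rubin-Terman basal-ganglia formulation;
#' the pyramidal cell is the regular-spiking cortical neuron of Pospischil and
#' colleagues (Traub-style kinetics with an M-current and a small
#' high-threshold Ca current); the dopaminergic cell is a soma-only pacemaker
#' carrying the fast Na, A-type, delayed-rectifier, SK, pump, T/N/L-type Ca
#' and triple-leak current inventory of nigral neuron models.
#'
#' @param type one of `"th"`, `"stn"`, `"gpe"`, `"gpi"`, `"py"`, `"da"`.
#' @param ... named overrides merged over the defaults.
#' @return a named list of class `cell_params`.
#' @examples
#' p <- cell_params("th")
#' p$g_na
#' @export
cell_params <- function(type = c("th", "stn", "gpe", "gpi", "py", "da"), ...) {
  type <- match.arg(type)
  p <- switch(type,
    th = list(
      cm = 1, g_l = 0.05, e_l = -70, g_na = 3, e_na = 50,
      g_k = 5, e_k = -75, g_t = 5, e_t = 0, i_app = 0
    ),
    stn = list(
      cm = 1, g_l = 2.25, e_l = -60, g_na = 37.5, e_na = 55,
      g_k = 45, e_k = -80, g_t = 0.5, g_ca = 0.5, e_ca = 140,
      g_ahp = 20, k1 = 15, k_ca = 22.5, eps = 2e-4,
      phi_h = 0.75, phi_n = 0.75, phi_r = 0.2, i_app = 0
    ),
    gpe = ,
    gpi = list(
      cm = 1, g_l = 0.1, e_l = -65, g_na = 120, e_na = 55,
      g_k = 30, e_k = -80, g_t = 0.5, g_ca = 0.15, e_ca = 120,
      g_ahp = 10, k1 = 10, k_ca = 15, eps = 1e-4,
      phi_h = 0.05, phi_n = 0.05, phi_r = 1, tau_r = 30, i_app = 0
    ),
    py = list(
      cm = 1, g_leak = 0.0205, e_leak = -70.3, g_na = 56, e_na = 50,
      g_kd = 6, e_k = -90, g_m = 0.075, tau_max = 608,
      g_lca = 0.1, e_ca = 120, v_t = -56.2, i_app = 0
    ),
    da = list(
      cm = 1, g_na = 110, e_na = 55, g_kdr = 18, e_k = -90,
      g_a = 4, g_sk = 1.5, k_sk = 0.3,
      g_cat = 0.15, g_can = 0.25, g_cal = 0.3, e_ca = 100,
      i_napump = 0.03, k_capump = 0.12,
      g_lna = 0.022, e_lna = 55, g_lk = 0.04, g_lca = 0.0005,
      f_ca = 0.05, tau_ca = 30, i_app = 0
    )
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s) for type '", type, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(over)] <- over
  }
  stopifnot(p$cm > 0)
  structure(p, class = "cell_params", cell_type = type)
}

#' Initial (rest-like) state vector for a cell type
#'
#' Gating variables are set to their steady-state values at the given
#' membrane potential; pooled calcium starts at a small positive value.
#'
#' @param type cell type as in [cell_params()].
#' @param v initial membrane potential (mV).
#' @return named numeric vector (`v`, gates, and `ca` where applicable).
#' @export
cell_state <- function(type = c("th", "stn", "gpe", "gpi", "py", "da"),
                       v = NULL) {
  type <- match.arg(type)
  if (is.null(v)) {
    v <- switch(type, th = -68, stn = -62, gpe = -66, gpi = -66,
                py = -71, da = -58)
  }
  switch(type,
    th = {
      k <- th_kinetics(v)
      c(v = v, h = k$h_inf, r = k$r_inf)
    },
    stn = {
      k <- stn_kinetics(v)
      c(v = v, h = k$h_inf, n = k$n_inf, r = k$r_inf, ca = 0.05)
    },
    gpe = ,
    gpi = {
      k <- gp_kinetics(v)
      c(v = v, h = k$h_inf, n = k$n_inf, r = k$r_inf, ca = 0.05)
    },
    py = {
      k <- py_kinetics(v, v_t = -56.2, tau_max = 608)
      c(v = v, m = k$m_inf, h = k$h_inf, n = k$n_inf,
        p = k$p_inf, q = k$q_inf, r = k$r_inf)
    },
    da = {
      k <- da_kinetics(v)
      c(v = v, m = k$m_inf, h = k$h_inf, n = k$n_inf,
        a = k$a_inf, b = k$b_inf, mt = k$mt_inf, ht = k$ht_inf,
        mn = k$mn_inf, ml = k$ml_inf, ca = 0.05)
    }
  )
}

validate_state <- function(state) {
  if (!all(is.finite(state))) {
    stop("invalid cell state: non-finite values in ",
         paste(names(state)[!is.finite(state)], collapse = ", "),
         call. = FALSE)
  }
  invisible(state)
}

sigmoid <- function(v, v_half, k) 1 / (1 + exp(-(v - v_half) / k))
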
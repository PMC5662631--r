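# Reference (pure-R) right-hand sides for the single-compartment cells.
# These are the package's definitional equations: the compiled fixed-step
# engine implements the same currents and is tested against adaptive-solver
# integrations of these functions.

th_kinetics <- function(v) {
  list(
    m_inf = sigmoid(v, -37, 7),
    h_inf = 1 / (1 + exp((v + 41) / 4)),
    p_inf = sigmoid(v, -60, 6.2),
    r_inf = 1 / (1 + exp((v + 84) / 4)),
    tau_h = 1 / (0.128 * exp(-(v + 46) / 18) + 4 / (1 + exp(-(v + 23) / 5))),
    tau_r = 0.15 * (28 + exp(-(v + 25) / 10.5))
  )
}

#' Thalamic relay cell dynamics
#'
#' Current-balance right-hand side for the thalamocortical relay neuron:
#' leak, Na, K and low-threshold T-type calcium currents, a pallidal
#' inhibitory synaptic current and a constant bias current. The cell is
#' silent at rest without input and fires rebound bursts after release
#' from hyperpolarization (T current).
#'
#' @param state named vector `c(v, h, r)`.
#' @param i_syn total synaptic current (uA/cm2, outward positive), i.e. the
#'   GPi->TH GABAergic term of the balance equation.
#' @param params a `cell_params("th")` list.
#' @return named vector of time derivatives (per ms).
#' @seealso [cell_params()], [cell_state()]
#' @export
th_rhs <- function(state, i_syn = 0, params = cell_params("th")) {
  validate_state(state)
  v <- state[["v"]]; h <- state[["h"]]; r <- state[["r"]]
  k <- th_kinetics(v)
  i_l <- params$g_l * (v - params$e_l)
  i_na <- params$g_na * k$m_inf^3 * h * (v - params$e_na)
  i_k <- params$g_k * (0.75 * (1 - h))^4 * (v - params$e_k)
  i_t <- params$g_t * k$p_inf^2 * r * (v - params$e_t)
  dv <- (-i_l - i_na - i_k - i_t - i_syn + params$i_app) / params$cm
  c(v = dv,
    h = (k$h_inf - h) / k$tau_h,
    r = (k$r_inf - r) / k$tau_r)
}

stn_kinetics <- function(v) {
  list(
    m_inf = sigmoid(v, -30, 15),
    h_inf = 1 / (1 + exp((v + 39) / 3.1)),
    n_inf = sigmoid(v, -32, 8),
    a_inf = sigmoid(v, -63, 7.8),
    s_inf = sigmoid(v, -39, 8),
    r_inf = 1 / (1 + exp((v + 67) / 2)),
    tau_h = 1 + 500 / (1 + exp((v + 57) / 3)),
    tau_n = 1 + 100 / (1 + exp((v + 80) / 26)),
    tau_r = 7.1 + 17.5 / (1 + exp((v - 68) / 2.2))
  )
}

stn_b_inf <- function(r) {
  1 / (1 + exp((r - 0.4) / 0.1)) - 1 / (1 + exp(4))
}

#' Subthalamic nucleus cell dynamics
#'
#' Leak, Na, K, low-threshold T-type and high-threshold Ca currents plus a
#' calcium-activated after-hyperpolarization current. Spontaneously active
#' at a low rate with zero synaptic input; pallidal inhibition and cortical
#' excitation enter through `i_syn`.
#'
#' @param state named vector `c(v, h, n, r, ca)`.
#' @param i_syn total synaptic current (uA/cm2, outward positive), the sum of
#'   the GPe->STN and cortex->STN terms.
#' @param params a `cell_params("stn")` list.
#' @return named vector of derivatives.
#' @export
stn_rhs <- function(state, i_syn = 0, params = cell_params("stn")) {
  validate_state(state)
  v <- state[["v"]]; h <- state[["h"]]; n <- state[["n"]]
  r <- state[["r"]]; ca <- state[["ca"]]
  k <- stn_kinetics(v)
  b <- stn_b_inf(r)
  i_l <- params$g_l * (v - params$e_l)
  i_na <- params$g_na * k$m_inf^3 * h * (v - params$e_na)
  i_k <- params$g_k * n^4 * (v - params$e_k)
  i_t <- params$g_t * k$a_inf^3 * b^2 * (v - params$e_ca)
  i_ca <- params$g_ca * k$s_inf^2 * (v - params$e_ca)
  i_ahp <- params$g_ahp * (v - params$e_k) * ca / (ca + params$k1)
  dv <- (-i_l - i_na - i_k - i_t - i_ca - i_ahp - i_syn + params$i_app) /
    params$cm
  c(v = dv,
    h = params$phi_h * (k$h_inf - h) / k$tau_h,
    n = params$phi_n * (k$n_inf - n) / k$tau_n,
    r = params$phi_r * (k$r_inf - r) / k$tau_r,
    ca = params$eps * (-i_ca - i_t - params$k_ca * ca))
}

gp_kinetics <- function(v) {
  list(
    m_inf = sigmoid(v, -37, 10),
    h_inf = 1 / (1 + exp((v + 58) / 12)),
    n_inf = sigmoid(v, -50, 14),
    a_inf = sigmoid(v, -57, 2),
    s_inf = sigmoid(v, -35, 2),
    r_inf = 1 / (1 + exp((v + 70) / 2)),
    tau_h = 0.05 + 0.27 / (1 + exp((v + 40) / 12)),
    tau_n = 0.05 + 0.27 / (1 + exp((v + 40) / 12))
  )
}

gp_rhs_core <- function(state, i_syn_total, params, app_sign = 1) {
  v <- state[["v"]]; h <- state[["h"]]; n <- state[["n"]]
  r <- state[["r"]]; ca <- state[["ca"]]
  k <- gp_kinetics(v)
  i_l <- params$g_l * (v - params$e_l)
  i_na <- params$g_na * k$m_inf^3 * h * (v - params$e_na)
  i_k <- params$g_k * n^4 * (v - params$e_k)
  i_t <- params$g_t * k$a_inf^3 * r * (v - params$e_ca)
  i_ca <- params$g_ca * k$s_inf^2 * (v - params$e_ca)
  i_ahp <- params$g_ahp * (v - params$e_k) * ca / (ca + params$k1)
  dv <- (-i_l - i_na - i_k - i_t - i_ca - i_ahp - i_syn_total +
           app_sign * params$i_app) / params$cm
  c(v = dv,
    h = params$phi_h * (k$h_inf - h) / k$tau_h,
    n = params$phi_n * (k$n_inf - n) / k$tau_n,
    r = params$phi_r * (k$r_inf - r) / params$tau_r,
    ca = params$eps * (-i_ca - i_t - params$k_ca * ca))
}

#' External pallidal (GPe) cell dynamics
#'
#' Same channel inventory as the STN cell family; synaptic input is passed
#' as a named list so the striatal (D2), intrapallidal and subthalamic terms
#' stay separately identifiable. Silent with zero input and zero bias.
#'
#' @param state named vector `c(v, h, n, r, ca)`.
#' @param i_syn named list or vector with elements `d2`, `gpe`, `stn`
#'   (uA/cm2, outward positive); missing elements count as zero.
#' @param params a `cell_params("gpe")` list.
#' @return named vector of derivatives.
#' @export
gpe_rhs <- function(state, i_syn = list(), params = cell_params("gpe")) {
  validate_state(state)
  tot <- sum(unlist(i_syn[names(i_syn) %in% c("d2", "gpe", "stn")]), 0)
  # the printed balance equation carries the GPe bias with a minus sign
  gp_rhs_core(state, tot, params, app_sign = -1)
}

#' Internal pallidal (GPi) cell dynamics
#'
#' As [gpe_rhs()] with the direct-pathway (D1), pallidal, intranuclear and
#' subthalamic synaptic terms. The constant bias current enters with a
#' positive sign in the balance equation.
#'
#' @param state named vector `c(v, h, n, r, ca)`.
#' @param i_syn named list or vector with elements `d1`, `gpe`, `gpi`, `stn`.
#' @param params a `cell_params("gpi")` list.
#' @return named vector of derivatives.
#' @export
gpi_rhs <- function(state, i_syn = list(), params = cell_params("gpi")) {
  validate_state(state)
  tot <- sum(unlist(i_syn[names(i_syn) %in% c("d1", "gpe", "gpi", "stn")]), 0)
  gp_rhs_core(state, tot, params)
}

py_kinetics <- function(v, v_t, tau_max) {
  vv <- v - v_t
  # Traub-style rates with the singularity-safe x/(exp(x)-1) form
  xexp <- function(x) ifelse(abs(x) < 1e-6, 1 - x / 2, x / (exp(x) - 1))
  am <- 0.32 * 4 * xexp((13 - vv) / 4)
  bm <- 0.28 * 5 * xexp((vv - 40) / 5)
  ah <- 0.128 * exp((17 - vv) / 18)
  bh <- 4 / (1 + exp((40 - vv) / 5))
  an <- 0.032 * 5 * xexp((15 - vv) / 5)
  bn <- 0.5 * exp((10 - vv) / 40)
  aq <- 0.055 * 3.8 * xexp((-27 - v) / 3.8)
  bq <- 0.94 * exp((-75 - v) / 17)
  ar <- 0.000457 * exp((-13 - v) / 50)
  br <- 0.0065 / (exp((-15 - v) / 28) + 1)
  p_inf <- sigmoid(v, -35, 10)
  tau_p <- tau_max / (3.3 * exp((v + 35) / 20) + exp(-(v + 35) / 20))
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn,
       aq = aq, bq = bq, ar = ar, br = br,
       m_inf = am / (am + bm), h_inf = ah / (ah + bh),
       n_inf = an / (an + bn), q_inf = aq / (aq + bq),
       r_inf = ar / (ar + br), p_inf = p_inf, tau_p = tau_p)
}

#' Cortical regular-spiking pyramidal cell dynamics
#'
#' Traub-kinetics Na/Kd spike currents, the slow voltage-dependent M-type
#' potassium current responsible for spike-frequency adaptation, a small
#' high-threshold calcium current, leak, thalamic feedback and external
#' stimulation.
#'
#' @param state named vector `c(v, m, h, n, p, q, r)`.
#' @param i_syn synaptic current (uA/cm2, outward positive), the TH->cortex
#'   feedback term.
#' @param i_ext external stimulus current at the current time (uA/cm2,
#'   inward positive, added to the bias current).
#' @param params a `cell_params("py")` list.
#' @return named vector of derivatives.
#' @export
py_rhs <- function(state, i_syn = 0, i_ext = 0, params = cell_params("py")) {
  validate_state(state)
  v <- state[["v"]]
  k <- py_kinetics(v, params$v_t, params$tau_max)
  m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  p <- state[["p"]]; q <- state[["q"]]; r <- state[["r"]]
  i_leak <- params$g_leak * (v - params$e_leak)
  i_na <- params$g_na * m^3 * h * (v - params$e_na)
  i_kd <- params$g_kd * n^4 * (v - params$e_k)
  i_m <- params$g_m * p * (v - params$e_k)
  i_lca <- params$g_lca * q^2 * r * (v - params$e_ca)
  dv <- (-i_leak - i_na - i_kd - i_m - i_lca - i_syn +
           params$i_app + i_ext) / params$cm
  c(v = dv,
    m = k$am * (1 - m) - k$bm * m,
    h = k$ah * (1 - h) - k$bh * h,
    n = k$an * (1 - n) - k$bn * n,
    p = (k$p_inf - p) / k$tau_p,
    q = k$aq * (1 - q) - k$bq * q,
    r = k$ar * (1 - r) - k$br * r)
}

da_kinetics <- function(v) {
  bell <- function(v, v0, ka, kb, t0, t1) {
    t0 + t1 / (exp((v - v0) / ka) + exp(-(v - v0) / kb))
  }
  list(
    m_inf = sigmoid(v, -38, 5.5), tau_m = 0.1,
    h_inf = sigmoid(v, -48, -6), tau_h = bell(v, -50, 10, 10, 0.5, 10),
    n_inf = sigmoid(v, -32, 10), tau_n = bell(v, -30, 15, 15, 1, 6),
    a_inf = sigmoid(v, -42, 8), tau_a = 1,
    b_inf = sigmoid(v, -63, -4), tau_b = 20,
    mt_inf = sigmoid(v, -55, 6), tau_mt = 3,
    ht_inf = sigmoid(v, -80, -5), tau_ht = 30,
    mn_inf = sigmoid(v, -25, 6), tau_mn = 2,
    ml_inf = sigmoid(v, -35, 5), tau_ml = 2
  )
}

#' Dopaminergic cell dynamics (soma only)
#'
#' Single-compartment nigral dopaminergic pacemaker with fast Na, A-type and
#' delayed-rectifier K, SK-type calcium-activated K, T/N/L-type calcium
#' currents, Na and Ca pump currents and three leak currents (Na, K, Ca).
#' Under default parameters the cell fires tonically at a few Hz with
#' regular interspike intervals.
#'
#' @param state named vector `c(v, m, h, n, a, b, mt, ht, mn, ml, ca)`.
#' @param i_ext external stimulus current (uA/cm2, inward positive).
#' @param params a `cell_params("da")` list.
#' @return named vector of derivatives.
#' @export
da_rhs <- function(state, i_ext = 0, params = cell_params("da")) {
  validate_state(state)
  v <- state[["v"]]; ca <- state[["ca"]]
  k <- da_kinetics(v)
  m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  a <- state[["a"]]; b <- state[["b"]]
  mt <- state[["mt"]]; ht <- state[["ht"]]
  mn <- state[["mn"]]; ml <- state[["ml"]]
  i_na <- params$g_na * m^3 * h * (v - params$e_na)
  i_kdr <- params$g_kdr * n^4 * (v - params$e_k)
  i_a <- params$g_a * a^3 * b * (v - params$e_k)
  z <- ca^4 / (ca^4 + params$k_sk^4)
  i_sk <- params$g_sk * z * (v - params$e_k)
  i_cat <- params$g_cat * mt^2 * ht * (v - params$e_ca)
  i_can <- params$g_can * mn^2 * (v - params$e_ca)
  i_cal <- params$g_cal * ml^2 * (v - params$e_ca)
  i_napump <- params$i_napump
  i_capump <- params$k_capump * ca / (ca + 0.5)
  i_lna <- params$g_lna * (v - params$e_lna)
  i_lk <- params$g_lk * (v - params$e_k)
  i_lca <- params$g_lca * (v - params$e_ca)
  dv <- (-i_na - i_a - i_kdr - i_sk - i_napump - i_capump -
           i_cat - i_cal - i_can - i_lna - i_lk - i_lca +
           params$i_app + i_ext) / params$cm
  c(v = dv,
    m = (k$m_inf - m) / k$tau_m,
    h = (k$h_inf - h) / k$tau_h,
    n = (k$n_inf - n) / k$tau_n,
    a = (k$a_inf - a) / k$tau_a,
    b = (k$b_inf - b) / k$tau_b,
    mt = (k$mt_inf - mt) / k$tau_mt,
    ht = (k$ht_inf - ht) / k$tau_ht,
    mn = (k$mn_inf - mn) / k$tau_mn,
    ml = (k$ml_inf - ml) / k$tau_ml,
    ca = -params$f_ca * (i_cat + i_can + i_cal) - ca / params$tau_ca)
}

#' Generic right-hand side dispatcher
#'
#' Convenience wrapper used by the oracle integrators: calls the cell-type
#' specific `*_rhs` with a scalar synaptic/external current.
#'
#' @param type cell type.
#' @param state state vector for that type.
#' @param i_syn synaptic current (outward positive).
#' @param i_ext external current (inward positive; PY and DA only).
#' @param params parameter list.
#' @return named derivative vector.
#' @export
cell_rhs <- function(type, state, i_syn = 0, i_ext = 0,
                     params = cell_params(type)) {
  # i_ext is inward positive; the basal-ganglia cells take a single
  # outward-positive synaptic argument, so external drive enters negated
  switch(type,
    th = th_rhs(state, i_syn - i_ext, params),
    stn = stn_rhs(state, i_syn - i_ext, params),
    gpe = gpe_rhs(state, list(d2 = i_syn - i_ext), params),
    gpi = gpi_rhs(state, list(d1 = i_syn - i_ext), params),
    py = py_rhs(state, i_syn, i_ext, params),
    da = da_rhs(state, i_ext, params),
    stop("unknown cell type: ", type)
  )
}
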
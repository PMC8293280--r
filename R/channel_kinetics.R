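#' @useDynLib kv4pace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default channel parameter set
#'
#' Reads the packaged channel configuration: Boltzmann gating parameters,
#' time-constant rules, reversal potentials and region-specific maximal
#' conductance densities for the six active conductances of the SNc
#' dopaminergic neuron model (fast sodium, delayed rectifier, A-type
#' potassium, HCN, L-type calcium, SK), plus passive and calcium constants
#' and the I_A/I_H coupling rules. All voltages are in mV, time constants in
#' ms, densities in pS/um^2, calcium in mM. Currents are outward-positive.
#'
#' @param path Optional path to an alternative YAML file with the same layout.
#' @return Nested list mirroring the YAML file.
#' @export
channel_defaults <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "channels.yaml", package = "kv4pace")
  }
  yaml::read_yaml(path)
}

#' Voltage-gate specification
#'
#' @param v50 Half-activation voltage (mV).
#' @param slope_k Boltzmann slope factor (mV, signed; positive slopes give
#'   curves increasing with voltage, negative decreasing).
#' @param exponent Nonnegative integer power of the gate in the current
#'   equation; 0 means the gate is absent and contributes a factor of 1.
#' @return Object of class `gate_spec`.
#' @export
gate_spec <- function(v50, slope_k, exponent = 1L) {
  stopifnot(is.finite(v50), is.finite(slope_k), slope_k != 0,
            exponent >= 0, exponent == as.integer(exponent))
  structure(list(v50 = v50, slope_k = slope_k, exponent = as.integer(exponent)),
            class = "gate_spec")
}

#' Boltzmann steady-state open fraction
#'
#' `1 / (1 + exp(-(v - v50) / k))`; monotone increasing in `v` when `k > 0`,
#' decreasing when `k < 0`.
#'
#' @param v Membrane potential (mV), vectorized.
#' @param gate A [gate_spec()].
#' @return Open fraction in `[0, 1]`.
#' @export
steady_state <- function(v, gate) {
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  1 / (1 + exp(-(v - gate$v50) / gate$slope_k))
}

#' Time-constant rule
#'
#' The model's gate time constants follow one of a fixed set of closed
#' forms: `constant` (a fixed value, ms), the voltage-dependent sodium
#' activation/inactivation (`na_m`, `na_h`), delayed-rectifier activation
#' (`kdr_m`), HCN activation (`h_m`), L-type calcium activation (`cal_m`),
#' or the A-current link (`ia_linked`: voltage-independent, with the
#' activation time constant tied to the inactivation one).
#'
#' @param rule_id One of `"constant"`, `"na_m"`, `"na_h"`, `"kdr_m"`,
#'   `"h_m"`, `"cal_m"`, `"ia_linked"`.
#' @param params Named list of constants the rule needs: `tau` for
#'   `constant`; `tau_h` and optionally `ratio` (default 50) plus
#'   `gate` (`"m"` or `"h"`) for `ia_linked`.
#' @return Object of class `tau_rule`.
#' @export
tau_rule <- function(rule_id, params = list()) {
  known <- c("constant", "na_m", "na_h", "kdr_m", "h_m", "cal_m", "ia_linked")
  if (!rule_id %in% known) stop("unknown time-constant rule: ", rule_id)
  structure(list(rule_id = rule_id, params = params), class = "tau_rule")
}

#' Evaluate a gate time constant
#'
#' @param v Membrane potential (mV), vectorized.
#' @param rule A [tau_rule()].
#' @return Time constant (ms), strictly positive.
#' @export
time_constant <- function(v, rule) {
  if (!inherits(rule, "tau_rule")) stop("rule must be a tau_rule")
  p <- rule$params
  switch(rule$rule_id,
    constant = rep_len(p$tau, length(v)),
    na_m = 0.01 + 0.33 / (1 + ((v + 20) / 30)^2),
    na_h = 0.7 + 16 / (1 + ((v + 50) / 8)^2),
    kdr_m = 4 * exp(-0.000729 * (v + 32)^2) + 4,
    h_m = 556 + 1100 * exp(-0.5 * (v / 11.06)^2),
    cal_m = tau_cal_m(v),
    ia_linked = {
      ratio <- if (is.null(p$ratio)) 50 else p$ratio
      gate <- if (is.null(p$gate)) "h" else p$gate
      tau <- if (identical(gate, "m")) p$tau_h / ratio else p$tau_h
      rep_len(tau, length(v))
    },
    stop("unknown time-constant rule: ", rule$rule_id)
  )
}

# L-type calcium activation time constant; the alpha-like term has a
# removable singularity at v = -39.26 handled via expm1
tau_cal_m <- function(v) {
  x <- v + 39.26
  a <- ifelse(abs(x) < 1e-7, 0.209 * 4.111, -0.209 * x / expm1(-x / 4.111))
  1 / (a + 0.944 * exp(-(v + 15.38) / 224.1))
}

#' Coupled A-current gating parameters
#'
#' The A-current half-inactivation voltage co-varies with the HCN activation
#' v50 (`v50_inact = slope * v50_h_act + intercept`); its activation v50 sits
#' a fixed shift above inactivation, and activation is a fixed factor faster
#' than inactivation.
#'
#' @param v50_h_act HCN activation half-voltage (mV); grid range
#'   `[-100, -80]`; values outside produce a warning (extrapolation).
#' @param tau_h A-current inactivation time constant (ms), `> 0`.
#' @param coupling List with `v50_slope`, `v50_intercept` (defaults 0.814,
#'   3.36).
#' @param link List with `ia_tau_ratio`, `ia_v50_shift` (defaults 50, 50).
#' @return List with `v50_inact`, `v50_act` (mV), `tau_m`, `tau_h` (ms).
#' @export
coupled_ia_params <- function(v50_h_act, tau_h,
                              coupling = list(v50_slope = 0.814,
                                              v50_intercept = 3.36),
                              link = list(ia_tau_ratio = 50,
                                          ia_v50_shift = 50)) {
  if (!is.finite(tau_h) || tau_h <= 0) stop("tau_h must be positive")
  if (v50_h_act < -100 || v50_h_act > -80) {
    warning("v50_h_act outside the calibrated [-100, -80] mV range; ",
            "extrapolating the v50 coupling")
  }
  v50_inact <- coupling$v50_slope * v50_h_act + coupling$v50_intercept
  list(v50_inact = v50_inact,
       v50_act = v50_inact + link$ia_v50_shift,
       tau_m = tau_h / link$ia_tau_ratio,
       tau_h = tau_h)
}

#' SK channel calcium-dependent open fraction
#'
#' Hill function of intracellular calcium,
#' `ca^n / (ca^n + kd^n)` with `n = 4` and `kd = 0.00019` mM.
#'
#' @param ca_i Intracellular calcium concentration (mM), `>= 0`, vectorized.
#' @param kd Half-activation concentration (mM).
#' @param n Hill coefficient.
#' @return Open fraction in `[0, 1]`, monotone increasing in `ca_i`.
#' @export
sk_open_fraction <- function(ca_i, kd = 0.00019, n = 4) {
  if (any(ca_i < 0)) stop("ca_i must be nonnegative")
  ca_i^n / (ca_i^n + kd^n)
}

#' Advance a gate by one time step
#'
#' Exact exponential relaxation of `dm/dt = (m_inf(v) - m) / tau(v)` at
#' frozen voltage: `m' = m_inf + (m - m_inf) * exp(-dt / tau)`.
#'
#' @param m Current gate value in `[0, 1]`.
#' @param v Membrane potential (mV) held over the step.
#' @param gate A [gate_spec()].
#' @param rule A [tau_rule()] for this gate.
#' @param dt Step (ms), `> 0`.
#' @return Updated gate value in `[0, 1]`.
#' @export
gate_step <- function(m, v, gate, rule, dt) {
  stopifnot(all(m >= 0), all(m <= 1), dt > 0)
  m_inf <- steady_state(v, gate)
  tau <- time_constant(v, rule)
  m_inf + (m - m_inf) * exp(-dt / tau)
}

#' Channel current density
#'
#' `gmax * m^a * h^b * (v - erev)`, outward-positive. A gate exponent of 0
#' encodes "no such gate" and contributes a factor of 1.
#'
#' @param v Membrane potential (mV).
#' @param m,h Gate open fractions in `[0, 1]`.
#' @param gmax Maximal conductance density (pS/um^2).
#' @param erev Reversal potential (mV).
#' @param a,b Gate exponents (nonnegative integers).
#' @return Current density in pS/um^2 * mV (fA/um^2), outward-positive.
#' @export
channel_current_density <- function(v, m, h, gmax, erev, a = 1L, b = 0L) {
  stopifnot(all(m >= 0 & m <= 1), all(h >= 0 & h <= 1), a >= 0, b >= 0)
  gmax * m^a * h^b * (v - erev)
}
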
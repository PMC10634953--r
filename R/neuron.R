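#' Ionic environment
#'
#' Ion concentrations, relative permeabilities, temperature and the
#' hypoxia-related midpoint shift that together determine reversal
#' potentials and gating rates.  Defaults reproduce standard in vitro slice
#' conditions: elevated bath potassium (8.5 mM) and subphysiological
#' temperature (27 degrees C).
#'
#' @param na_in,na_out Intra/extracellular sodium (mM).
#' @param k_in,k_bath Intracellular and bath potassium (mM).  `k_bath` sets
#'   the potassium and leak reversal potentials and, through
#'   [mu_leak()], the mean of the leak-conductance distribution.
#' @param p_na,p_k Relative permeabilities of the leak to sodium and
#'   potassium (dimensionless).
#' @param temperature Bath temperature (degrees C).
#' @param dv_half_na Additive shift (mV) applied to the (in)activation
#'   midpoints of the fast sodium and spike-height currents; negative
#'   values model the acute hypoxic hyperpolarizing shift.
#' @param e_syn Excitatory synaptic reversal potential (mV).
#' @param e_ca Calcium reversal potential (mV); inert while `g_ca = 0`.
#' @param t_ref Reference temperature (degrees C) at which gating time
#'   constants and capacitance take their tabulated values.
#' @param q10 Temperature coefficient applied to all gating, synaptic and
#'   depression rate constants.
#' @returns An object of class `ion_env`.
#' @export
ion_environment <- function(na_in = 15, na_out = 120, k_in = 125,
                            k_bath = 8.5, p_na = 1, p_k = 42,
                            temperature = 27, dv_half_na = 0,
                            e_syn = 0, e_ca = 40, t_ref = 27, q10 = 1.5) {
  if (any(c(na_in, na_out, k_in, k_bath) <= 0))
    stop("ion concentrations must be positive", call. = FALSE)
  stopifnot(p_na > 0, p_k > 0, q10 > 0)
  structure(
    list(na_in = na_in, na_out = na_out, k_in = k_in, k_bath = k_bath,
         p_na = p_na, p_k = p_k, temperature = temperature,
         dv_half_na = dv_half_na, e_syn = e_syn, e_ca = e_ca,
         t_ref = t_ref, q10 = q10),
    class = "ion_env"
  )
}

#' Nernst/GHK-style reversal potentials
#'
#' `E_Na = 26.54 ln(Na_out / Na_in)`, `E_K = 26.54 ln(K_bath / K_in)`, and a
#' permeability-weighted leak reversal
#' `E_Leak = -26.54 ln[(P_Na Na_in + P_K K_in) / (P_Na Na_out + P_K K_bath)]`.
#'
#' @param env An [ion_environment()].
#' @returns A one-row tibble with columns `e_na`, `e_k`, `e_leak` (mV).
#' @export
reversal_potentials <- function(env) {
  stopifnot(inherits(env, "ion_env"))
  tibble::tibble(
    e_na = 26.54 * log(env$na_out / env$na_in),
    e_k = 26.54 * log(env$k_bath / env$k_in),
    e_leak = -26.54 * log((env$p_na * env$na_in + env$p_k * env$k_in) /
                          (env$p_na * env$na_out + env$p_k * env$k_bath))
  )
}

#' Mean leak conductance implied by the bath potassium concentration
#'
#' `mu_leak = exp((K_bath - 3.425) / 4.05)` nS; at the standard in vitro
#' bath (8.5 mM) this is about 3.5 nS.
#'
#' @param k_bath Bath potassium (mM), vectorised.
#' @returns Mean leak conductance (nS).
#' @export
mu_leak <- function(k_bath) exp((k_bath - 3.425) / 4.05)

#' Full set of gating kinetics for one neuron
#'
#' Fast sodium, delayed rectifier, persistent sodium and the two
#' spike-shape currents.  The spike-shape current kinetics (activation of
#' both, inactivation of the spike-height current) come from the package
#' calibration (see [calibrate_spike_currents()]).
#'
#' @param m_spk,m_ahp Activation kinetics for the spike-height and AHP
#'   currents; defaults are the calibrated package values.
#' @param h_spk Inactivation kinetics of the spike-height current.
#' @returns Named list of kinetics objects keyed `m_na`, `h_na`, `m_k`,
#'   `m_spk`, `h_spk`, `m_ahp`, `m_nap`, `h_nap`, `m_ca`, `h_ca`.
#' @export
default_kinetics <- function(m_spk = spk_activation_kinetics(),
                             m_ahp = ahp_activation_kinetics(),
                             h_spk = spk_inactivation_kinetics()) {
  list(
    m_na = gate_kinetics(-43.8, 6.0, 0.25, -43.8, 14.0),
    h_na = gate_kinetics(-67.5, -11.8, 8.46, -67.5, 12.8),
    m_k = rectifier_kinetics(0.011, 44.0, 5.0, 0.17, 49.0, 40.0),
    m_spk = m_spk,
    h_spk = h_spk,
    m_ahp = m_ahp,
    m_nap = gate_kinetics(-47.1, 3.1, 1.0, -47.1, 6.2),
    h_nap = gate_kinetics(-60.0, -9.0, 5000, -60.0, 9.0),
    m_ca = NULL,
    h_ca = NULL
  )
}

#' Single-neuron parameters
#'
#' Maximal conductances (nS) and membrane capacitance (pF) for one model
#' neuron, plus the gating kinetics shared by its currents.  Defaults are
#' the standard parameter set; `g_leak` defaults to the mean implied by the
#' standard bath potassium.
#'
#' @param c_m Membrane capacitance (pF).
#' @param g_na,g_k Fast sodium and delayed-rectifier conductances.
#' @param g_spk,g_ahp Spike-height and afterhyperpolarization conductances;
#'   zero leaves spike shape at its baseline.
#' @param g_nap Persistent sodium conductance.
#' @param g_ca Calcium conductance (defaults to 0 and contributes nothing;
#'   supply `m_ca`/`h_ca` kinetics to enable it).
#' @param g_leak Potassium-dominated leak conductance.
#' @param g_tonic Tonic excitatory drive conductance (the excitability axis).
#' @param kinetics Named kinetics list as from [default_kinetics()].
#' @returns An object of class `neuron_params`.
#' @export
neuron_parameters <- function(c_m = 36, g_na = 150, g_k = 220, g_spk = 0,
                              g_ahp = 0, g_nap = 3.33, g_ca = 0,
                              g_leak = mu_leak(8.5), g_tonic = 0,
                              kinetics = default_kinetics()) {
  g <- c(g_na, g_k, g_spk, g_ahp, g_nap, g_ca, g_leak, g_tonic)
  if (any(g < 0)) stop("conductances must be nonnegative", call. = FALSE)
  stopifnot(c_m > 0)
  structure(
    list(c_m = c_m, g_na = g_na, g_k = g_k, g_spk = g_spk, g_ahp = g_ahp,
         g_nap = g_nap, g_ca = g_ca, g_leak = g_leak, g_tonic = g_tonic,
         kinetics = kinetics),
    class = "neuron_params"
  )
}

#' Canonical intrinsic burster
#'
#' Convenience constructor for the reference pacemaker used throughout the
#' spike-shape experiments: `g_NaP` at the population mean (3.33 nS) and
#' `g_Leak` at the mean implied by the standard bath (about 3.5 nS).
#'
#' @param ... Overrides passed to [neuron_parameters()].
#' @export
canonical_burster <- function(...) {
  neuron_parameters(g_nap = 3.33, g_leak = mu_leak(8.5), ...)
}

#' Initial neuron state at steady state
#'
#' Gate variables set to their steady-state values at the holding voltage,
#' depression at its ceiling.
#'
#' @param params A [neuron_parameters()] object.
#' @param env An [ion_environment()].
#' @param v Holding potential (mV).
#' @returns A list with `v`, named gate values and depression `d`.
#' @export
neuron_state <- function(params, env = ion_environment(), v = -60) {
  kin <- params$kinetics
  shift <- env$dv_half_na
  shifted <- c("m_na", "h_na", "m_spk", "h_spk")
  gates <- list()
  for (nm in names(kin)) {
    k <- kin[[nm]]
    if (is.null(k)) next
    gates[[nm]] <-
      if (inherits(k, "rectifier_kinetics")) rectifier_activation(k, v)$m_inf
      else steady_state(k, v, shift = if (nm %in% shifted) shift else 0)
  }
  c(list(v = v), gates, list(d = 1))
}

#' Right-hand side of the single-neuron membrane equation
#'
#' Reference (pure R) evaluation of the membrane ODE: capacitive balance of
#' fast sodium (m^3 h), delayed rectifier (m^4), spike-height, AHP,
#' persistent sodium, calcium, leak, tonic and synaptic currents, and the
#' first-order relaxation of every gate with temperature-scaled time
#' constants.  The C++ engine integrates the same system; this function is
#' the slow, readable form used for verification and for exploring the
#' vector field.
#'
#' @param state A state list as from [neuron_state()].
#' @param params A [neuron_parameters()] object.
#' @param env An [ion_environment()].
#' @param g_syn Total dynamic synaptic conductance impinging on the neuron
#'   (nS), excluding the tonic drive.
#' @returns A list with `dv` (mV/ms), named gate derivatives `dgates`
#'   (1/ms), and the individual currents (pA) in `currents`.
#' @export
membrane_derivative <- function(state, params, env = ion_environment(),
                                g_syn = 0) {
  rev <- reversal_potentials(env)
  kin <- params$kinetics
  v <- state$v
  shift <- env$dv_half_na
  rate_mult <- env$q10^((env$temperature - env$t_ref) / 10)
  cap <- params$c_m * 1.003^(env$temperature - env$t_ref)

  cur <- c(
    i_na = params$g_na * state$m_na^3 * state$h_na * (v - rev$e_na),
    i_k = params$g_k * state$m_k^4 * (v - rev$e_k),
    i_spk = if (!is.null(kin$m_spk) && params$g_spk > 0)
      params$g_spk * state$m_spk * state$h_spk * (v - rev$e_na) else 0,
    i_ahp = if (!is.null(kin$m_ahp) && params$g_ahp > 0)
      params$g_ahp * state$m_ahp * (v - rev$e_k) else 0,
    i_nap = params$g_nap * state$m_nap * state$h_nap * (v - rev$e_na),
    i_ca = if (params$g_ca > 0)
      params$g_ca * state$m_ca * state$h_ca * (v - env$e_ca) else 0,
    i_leak = params$g_leak * (v - rev$e_leak),
    i_tonic = params$g_tonic * (v - env$e_syn),
    i_syn = g_syn * (v - env$e_syn)
  )

  shifted <- c("m_na", "h_na", "m_spk", "h_spk")
  dgates <- list()
  for (nm in names(kin)) {
    k <- kin[[nm]]
    if (is.null(k) || is.null(state[[nm]])) next
    if (inherits(k, "rectifier_kinetics")) {
      ra <- rectifier_activation(k, v)
      inf <- ra$m_inf; tau <- ra$tau
    } else {
      s <- if (nm %in% shifted) shift else 0
      inf <- steady_state(k, v, s)
      tau <- time_constant(k, v, s)
    }
    dgates[[nm]] <- rate_mult * (inf - state[[nm]]) / tau
  }

  list(dv = -sum(cur) / cap, dgates = dgates, currents = cur)
}
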
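#' Voltage-dependent gating kinetics
#'
#' Most gated currents in the model use a five-parameter description of one
#' gating variable: a Boltzmann sigmoid for the steady state and a
#' hyperbolic-secant (1/cosh) bell for the voltage-dependent time constant.
#' The sign of `k_x` encodes direction: positive for activation gates,
#' negative for inactivation gates.
#'
#' @param x_half Voltage midpoint of the steady-state sigmoid (mV).
#' @param k_x Slope factor (mV); must be nonzero.  Negative values give an
#'   inactivation gate (steady state decreasing in V).
#' @param tau_max Peak time constant (ms); must be positive.
#' @param tau_half Voltage at which the time constant peaks (mV).  Defaults
#'   to `x_half`.
#' @param k_tau Width of the time-constant bell (mV); must be positive.
#' @returns An object of class `gate_kinetics`.
#' @examples
#' nap_m <- gate_kinetics(-47.1, 3.1, 1.0, -47.1, 6.2)
#' steady_state(nap_m, -47.1) # 0.5 at the midpoint
#' @export
gate_kinetics <- function(x_half, k_x, tau_max, tau_half = x_half, k_tau) {
  stopifnot(is.finite(x_half), k_x != 0, tau_max > 0, k_tau > 0)
  structure(
    list(x_half = x_half, k_x = k_x, tau_max = tau_max,
         tau_half = tau_half, k_tau = k_tau, fixed_tau = FALSE),
    class = "gate_kinetics"
  )
}

#' Gating kinetics with a voltage-independent time constant
#'
#' Used for the afterhyperpolarization current's activation gate, whose
#' relaxation is modelled with a single fixed time constant.
#'
#' @inheritParams gate_kinetics
#' @param tau Fixed time constant (ms).
#' @returns An object of class `gate_kinetics`.
#' @export
gate_kinetics_fixed_tau <- function(x_half, k_x, tau) {
  stopifnot(is.finite(x_half), k_x != 0, tau > 0)
  structure(
    list(x_half = x_half, k_x = k_x, tau_max = tau,
         tau_half = NA_real_, k_tau = NA_real_, fixed_tau = TRUE),
    class = "gate_kinetics"
  )
}

#' Delayed-rectifier rate-constant kinetics
#'
#' The delayed-rectifier potassium current uses classical forward/backward
#' rate constants: a linear-over-exponential form for alpha (with a
#' removable singularity at `V = -B_alpha`) and a pure exponential for beta.
#'
#' @param A_alpha Rate scale of the forward rate (1/ms/mV).
#' @param B_alpha Voltage offset of the forward rate (mV).
#' @param k_alpha Slope of the forward rate (mV), positive.
#' @param A_beta Rate scale of the backward rate (1/ms).
#' @param B_beta Voltage offset of the backward rate (mV).
#' @param k_beta Slope of the backward rate (mV), positive.
#' @returns An object of class `rectifier_kinetics`.
#' @export
rectifier_kinetics <- function(A_alpha, B_alpha, k_alpha, A_beta, B_beta, k_beta) {
  stopifnot(A_alpha > 0, A_beta > 0, k_alpha > 0, k_beta > 0)
  structure(
    list(A_alpha = A_alpha, B_alpha = B_alpha, k_alpha = k_alpha,
         A_beta = A_beta, B_beta = B_beta, k_beta = k_beta),
    class = "rectifier_kinetics"
  )
}

clip500 <- function(x) pmin(pmax(x, -500), 500)

#' Steady-state (in)activation of a gate
#'
#' Boltzmann sigmoid `1 / (1 + exp(-(V - x_half - shift) / k_x))`.  A
#' positive `shift` translates the midpoint depolarized; hypoxia protocols
#' use a negative shift on the fast-sodium gates.
#'
#' @param kin A [gate_kinetics()] object.
#' @param v Membrane potential (mV), vectorised.
#' @param shift Additive translation of the midpoint (mV).
#' @returns Steady-state gate value in (0, 1).
#' @export
steady_state <- function(kin, v, shift = 0) {
  stopifnot(inherits(kin, "gate_kinetics"))
  1 / (1 + exp(clip500(-(v - (kin$x_half + shift)) / kin$k_x)))
}

#' Voltage-dependent time constant of a gate
#'
#' `tau_max / cosh((V - tau_half - shift) / k_tau)`; peaks at
#' `tau_half + shift` where it equals `tau_max`.  For fixed-tau gates the
#' value is constant.
#'
#' @inheritParams steady_state
#' @returns Time constant (ms).
#' @export
time_constant <- function(kin, v, shift = 0) {
  stopifnot(inherits(kin, "gate_kinetics"))
  if (isTRUE(kin$fixed_tau)) return(rep_len(kin$tau_max, length(v)))
  kin$tau_max / cosh(clip500((v - (kin$tau_half + shift)) / kin$k_tau))
}

#' Delayed-rectifier steady state and time constant
#'
#' Computes `m_inf = alpha / (alpha + beta)` and `tau = 1 / (alpha + beta)`.
#' The forward rate's removable singularity at `V = -B_alpha` is evaluated
#' by its analytic limit `A_alpha * k_alpha`.
#'
#' @param kin A [rectifier_kinetics()] object.
#' @param v Membrane potential (mV), vectorised.
#' @returns A list with elements `m_inf`, `tau`, `alpha`, `beta`.
#' @export
rectifier_activation <- function(kin, v) {
  stopifnot(inherits(kin, "rectifier_kinetics"))
  u <- v + kin$B_alpha
  alpha <- ifelse(
    abs(u) < 1e-7,
    kin$A_alpha * kin$k_alpha,
    kin$A_alpha * u / (1 - exp(clip500(-u / kin$k_alpha)))
  )
  beta <- kin$A_beta * exp(clip500(-(v + kin$B_beta) / kin$k_beta))
  list(m_inf = alpha / (alpha + beta), tau = 1 / (alpha + beta),
       alpha = alpha, beta = beta)
}

# serialize a gate_kinetics / rectifier_kinetics object for the C++ engine
kin_to_engine <- function(kin) {
  if (is.null(kin)) return(NULL)
  if (inherits(kin, "rectifier_kinetics")) {
    return(list(type = "rectifier",
                p = c(kin$A_alpha, kin$B_alpha, kin$k_alpha,
                      kin$A_beta, kin$B_beta, kin$k_beta)))
  }
  stopifnot(inherits(kin, "gate_kinetics"))
  if (isTRUE(kin$fixed_tau)) {
    list(type = "sigmoid_fixed_tau", p = c(kin$x_half, kin$k_x, kin$tau_max))
  } else {
    list(type = "sigmoid",
         p = c(kin$x_half, kin$k_x, kin$tau_max, kin$tau_half, kin$k_tau))
  }
}
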
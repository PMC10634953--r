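#' Network construction parameters
#'
#' Describes how a heterogeneous excitatory population and its random
#' connectome are sampled.  Defaults give the standard 100-neuron network:
#' 13% directed connection probability, uniform weights up to 0.2 nS, and a
#' bivariate-normal `(g_NaP, g_Leak)` distribution with correlation 0.8.
#'
#' @param n Number of neurons.
#' @param p_syn Directed connection probability in `[0, 1]`.
#' @param w_max Maximal synaptic weight (nS); weights are `U(0, w_max)`.
#' @param mu_nap,sigma_nap Mean and s.d. of the persistent-sodium
#'   conductance distribution (nS).
#' @param rho Correlation between `g_NaP` and `g_Leak` (|rho| < 1).
#' @param sigma_leak_frac Leak-conductance s.d. as a fraction of its mean.
#' @param g_spk_dist,g_ahp_dist Spike-shape conductances: a single number
#'   for a constant value, or a length-2 vector `c(lo, hi)` for a uniform
#'   range per neuron.
#' @param seed RNG seed controlling the whole realization.
#' @returns An object of class `network_spec`.
#' @export
network_spec <- function(n = 100, p_syn = 0.13, w_max = 0.2,
                         mu_nap = 3.33, sigma_nap = 0.75, rho = 0.8,
                         sigma_leak_frac = 0.05,
                         g_spk_dist = 0, g_ahp_dist = 0, seed = 1L) {
  if (p_syn < 0 || p_syn > 1) stop("p_syn must be in [0, 1]", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  stopifnot(n >= 1, w_max >= 0, sigma_nap > 0, sigma_leak_frac >= 0,
            length(g_spk_dist) %in% 1:2, length(g_ahp_dist) %in% 1:2)
  structure(
    list(n = as.integer(n), p_syn = p_syn, w_max = w_max, mu_nap = mu_nap,
         sigma_nap = sigma_nap, rho = rho, sigma_leak_frac = sigma_leak_frac,
         g_spk_dist = g_spk_dist, g_ahp_dist = g_ahp_dist,
         seed = as.integer(seed)),
    class = "network_spec"
  )
}

# draw from a normal truncated at zero by resampling
rnorm_trunc0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < 0)
  }
  x
}

draw_dist <- function(n, dist) {
  if (length(dist) == 1) rep(dist, n) else runif(n, dist[1], dist[2])
}

#' Sample a heterogeneous neuron population
#'
#' `g_NaP` is drawn from a normal distribution (truncated at zero) and
#' `g_Leak` from the conditional normal implied by a bivariate-normal model
#' with correlation `rho`: conditional mean
#' `mu_leak + rho (sigma_leak / sigma_nap) (g_NaP - mu_nap)` and s.d.
#' `sqrt(1 - rho^2) sigma_leak`.  The leak mean is tied to the bath
#' potassium via [mu_leak()].
#'
#' @param spec A [network_spec()].
#' @param env An [ion_environment()]; supplies `k_bath`.
#' @returns A tibble with one row per neuron: `neuron`, `g_nap`, `g_leak`,
#'   `g_spk`, `g_ahp`.
#' @export
sample_population <- function(spec, env = ion_environment()) {
  stopifnot(inherits(spec, "network_spec"))
  local_seed(spec$seed, {
    ml <- mu_leak(env$k_bath)
    sl <- spec$sigma_leak_frac * ml
    g_nap <- rnorm_trunc0(spec$n, spec$mu_nap, spec$sigma_nap)
    mu_star <- ml + spec$rho * (sl / spec$sigma_nap) * (g_nap - spec$mu_nap)
    sd_star <- sqrt(1 - spec$rho^2) * sl
    g_leak <- pmax(rnorm(spec$n, mu_star, sd_star), 0)
    tibble::tibble(
      neuron = seq_len(spec$n),
      g_nap = g_nap,
      g_leak = g_leak,
      g_spk = draw_dist(spec$n, spec$g_spk_dist),
      g_ahp = draw_dist(spec$n, spec$g_ahp_dist)
    )
  })
}

#' Sample a random connectome
#'
#' Each ordered pair `(j, i)`, `j != i`, is connected independently with
#' probability `p_syn`; connected edges get a weight drawn uniformly from
#' `(0, w_max)`.
#'
#' @param spec A [network_spec()].
#' @returns A list with the binary connectivity matrix `c_mat`, the weight
#'   matrix `w` (both `n x n`, zero diagonal, entry `[j, i]` is the edge
#'   from j to i), and a tidy `edges` tibble (`pre`, `post`, `weight`).
#' @export
sample_connectome <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  n <- spec$n
  local_seed(spec$seed + 1L, {
    c_mat <- matrix(as.numeric(runif(n * n) < spec$p_syn), n, n)
    diag(c_mat) <- 0
    w <- matrix(0, n, n)
    idx <- which(c_mat == 1)
    w[idx] <- runif(length(idx), 0, spec$w_max)
    edges <- tibble::tibble(
      pre = (idx - 1L) %% n + 1L,
      post = (idx - 1L) %/% n + 1L,
      weight = w[idx]
    )
    list(c_mat = c_mat, w = w, edges = edges)
  })
}

#' Short-term synaptic depression parameters
#'
#' Mean-field depression: each presynaptic spike multiplies the depression
#' scalar by `1 - alpha_d`; between spikes it recovers exponentially toward
#' `d0` with time constant `tau_d`.  `tau_syn` is the decay of the
#' postsynaptic conductance transient.
#'
#' @param tau_syn Synaptic decay constant (ms).
#' @param d0 Depression ceiling (dimensionless).
#' @param tau_d Recovery time constant (ms).
#' @param alpha_d Fractional depression per spike in `[0, 1]`.
#' @export
synapse_dynamics <- function(tau_syn = 5, d0 = 1, tau_d = 1000,
                             alpha_d = 0.2) {
  stopifnot(tau_syn > 0, tau_d > 0, alpha_d >= 0, alpha_d <= 1, d0 > 0)
  structure(list(tau_syn = tau_syn, d0 = d0, tau_d = tau_d,
                 alpha_d = alpha_d),
            class = "synapse_dynamics")
}

#' One Euler step of the depression variable
#'
#' @param d Current depression value(s).
#' @param spiked Logical; did the presynaptic neuron spike this step?
#' @param dt Step (ms).
#' @param dyn A [synapse_dynamics()] object.
#' @returns Updated depression value(s).
#' @export
depression_step <- function(d, spiked, dt, dyn = synapse_dynamics()) {
  d <- d + dt * (dyn$d0 - d) / dyn$tau_d
  d <- pmin(d, dyn$d0)
  ifelse(spiked, d * (1 - dyn$alpha_d), d)
}

#' Steady-state depression under periodic spiking
#'
#' Closed-form fixed point of the per-cycle map for a neuron spiking at a
#' fixed interval `t_isi`: the pre-spike depression converges to
#' `(1 - e) / (1 - (1 - alpha_d) e)` with `e = exp(-t_isi / tau_d)`.
#'
#' @param t_isi Inter-spike interval (ms).
#' @param dyn A [synapse_dynamics()] object.
#' @returns Pre-spike steady-state depression (units of `d0`).
#' @export
depression_fixed_point <- function(t_isi, dyn = synapse_dynamics()) {
  e <- exp(-t_isi / dyn$tau_d)
  dyn$d0 * (1 - e) / (1 - (1 - dyn$alpha_d) * e)
}

#' One step of the aggregated synaptic drive
#'
#' Each postsynaptic neuron carries a single exponentially decaying
#' accumulator; a presynaptic spike in neuron j adds `W[j, i] * D[j]` to
#' every target i instantaneously (zero transmission delay).  This is
#' exactly equivalent to summing per-event exponentials with one shared
#' decay constant.
#'
#' @param drive Numeric vector of per-neuron accumulated drive (nS).
#' @param spiked Logical or integer vector marking presynaptic spikes this
#'   step.
#' @param d Per-neuron depression values at spike time.
#' @param w Weight matrix (`[j, i]` = j onto i).
#' @param dt Step (ms).
#' @param dyn A [synapse_dynamics()] object.
#' @returns Updated drive vector.
#' @export
synaptic_conductance_step <- function(drive, spiked, d, w, dt,
                                      dyn = synapse_dynamics()) {
  drive <- drive * exp(-dt / dyn$tau_syn)
  js <- if (is.logical(spiked)) which(spiked) else as.integer(spiked)
  for (j in js) drive <- drive + w[j, ] * d[j]
  drive
}

#' Build a full network realization
#'
#' Samples the population and connectome under the spec's seed and packages
#' them with the environment, kinetics and synaptic dynamics into a
#' simulatable object.
#'
#' @param spec A [network_spec()].
#' @param env An [ion_environment()].
#' @param kinetics Shared gating kinetics, as from [default_kinetics()].
#' @param dyn A [synapse_dynamics()] object.
#' @param g_tonic Tonic drive applied to every neuron (nS); scalar or
#'   per-neuron vector.
#' @returns An object of class `prebotc_network`: a list with the `neurons`
#'   tibble (all conductances), weight matrix `w`, and the shared
#'   `spec`, `env`, `kinetics`, `dyn`.
#' @export
build_network <- function(spec = network_spec(), env = ion_environment(),
                          kinetics = default_kinetics(),
                          dyn = synapse_dynamics(), g_tonic = 0) {
  pop <- sample_population(spec, env)
  con <- sample_connectome(spec)
  neurons <- dplyr::mutate(
    pop,
    c_m = 36, g_na = 150, g_k = 220, g_ca = 0,
    g_tonic = rep_len(g_tonic, spec$n)
  )
  structure(
    list(neurons = neurons, w = con$w, edges = con$edges, spec = spec,
         env = env, kinetics = kinetics, dyn = dyn),
    class = "prebotc_network"
  )
}

#' @export
print.prebotc_network <- function(x, ...) {
  cat("<prebotc_network> ", nrow(x$neurons), " neurons, ",
      nrow(x$edges), " edges (seed ", x$spec$seed, ")\n", sep = "")
  cat("  g_NaP: mean ", round(mean(x$neurons$g_nap), 2), " nS; g_Leak: mean ",
      round(mean(x$neurons$g_leak), 2), " nS\n", sep = "")
  invisible(x)
}

#' Tidy a network realization into its per-neuron parameter table
#'
#' @param x A `prebotc_network`.
#' @param ... Unused.
#' @returns The `neurons` tibble (one row per neuron with all conductances).
#' @export
tidy.prebotc_network <- function(x, ...) x$neurons
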
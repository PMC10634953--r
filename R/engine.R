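#' Simulation configuration
#'
#' @param dt Integration step (ms).  The model is integrated by explicit
#'   first-order Euler at this fixed step; 0.025 ms is the standard value.
#' @param duration Total simulated time (ms).
#' @param transient Initial window (ms) discarded by downstream analyses.
#' @param record_dt Trace decimation (ms); 0 records spikes only.
#' @param record_neurons Integer ids of neurons whose membrane potential is
#'   stored when traces are recorded.
#' @param init_v Initial membrane potential (mV); gates start at their
#'   steady state for this voltage.
#' @param spike_threshold Spike detection threshold (mV): a spike is logged
#'   at the first step where V increases through this value.
#' @param refractory Lockout (ms) after each logged spike to suppress
#'   numerical double-crossings.
#' @export
simulation_config <- function(dt = 0.025, duration = 10000, transient = 0,
                              record_dt = 0, record_neurons = integer(0),
                              init_v = -60, spike_threshold = -35,
                              refractory = 1) {
  stopifnot(dt > 0, duration >= 0, transient < duration || duration == 0)
  structure(
    list(dt = dt, duration = duration, transient = transient,
         record_dt = record_dt,
         record_neurons = as.integer(record_neurons), init_v = init_v,
         spike_threshold = spike_threshold, refractory = refractory),
    class = "simulation_config"
  )
}

env_to_engine <- function(env, c_m) {
  list(cap = c_m, e_syn = env$e_syn, e_ca = env$e_ca, na_in = env$na_in,
       na_out = env$na_out, k_in = env$k_in, k_bath = env$k_bath,
       p_na = env$p_na, p_k = env$p_k, temperature = env$temperature,
       t_ref = env$t_ref, q10 = env$q10, dv_half_na = env$dv_half_na)
}

cond_matrix <- function(neurons) {
  as.matrix(neurons[, c("g_na", "g_k", "g_spk", "g_ahp", "g_nap", "g_ca",
                        "g_leak", "g_tonic")])
}

run_engine <- function(cond, kinetics, env, w, dyn, cfg,
                       schedule = list(), clamps = list(), c_m = 36) {
  res <- sim_engine_cpp(
    cond,
    lapply(kinetics, kin_to_engine),
    env_to_engine(env, c_m),
    list(w = w, tau_syn = dyn$tau_syn, d0 = dyn$d0, tau_d = dyn$tau_d,
         alpha_d = dyn$alpha_d),
    list(dt = cfg$dt, duration = cfg$duration,
         spike_threshold = cfg$spike_threshold, refractory = cfg$refractory,
         record_dt = cfg$record_dt, record_idx = cfg$record_neurons,
         init_v = cfg$init_v),
    schedule, clamps
  )
  action_names <- c("syn_off", "freeze_mnap_nonspiked", "freeze_hnap",
                    "freeze_d", "freeze_hnap_d")
  traces <- NULL
  if (!is.null(res$trace_time)) {
    traces <- tibble::tibble(
      time = res$trace_time,
      mean_hnap = res$trace_mean_hnap,
      mean_mnap = res$trace_mean_mnap,
      mean_d = res$trace_mean_d,
      mean_drive = res$trace_mean_drive
    )
    vm <- res$trace_v
    if (ncol(vm) > 0) {
      colnames(vm) <- paste0("v_", cfg$record_neurons)
      traces <- dplyr::bind_cols(traces, tibble::as_tibble(vm))
    }
  }
  structure(
    list(
      spikes = tibble::tibble(neuron = res$spike_neuron,
                              time = res$spike_time),
      traces = traces,
      events = tibble::tibble(time = res$event_time,
                              action = action_names[res$event_action]),
      trigger_time = res$trigger_time,
      final = list(v = res$final_v, d = res$final_d,
                   gates = res$final_gates),
      n = nrow(cond), dt = cfg$dt, duration = cfg$duration,
      transient = cfg$transient
    ),
    class = "sim_record"
  )
}

#' Simulate a coupled network
#'
#' Integrates the full network (membrane equations, gating, aggregated
#' synaptic drive with short-term depression) by forward Euler at a fixed
#' step.  Spikes are logged at upward threshold crossings; optional clamp
#' events can disable synapses or freeze persistent-sodium gates and
#' depression, either at a wall-clock time or at detected burst initiation.
#'
#' @param network A [build_network()] object.
#' @param config A [simulation_config()].
#' @param schedule Named list of piecewise-linear parameter time courses
#'   (each `list(time =, value =)` in ms); recognised names are `dv_half`,
#'   `na_in`, `temperature`, `k_bath`, `g_tonic_add`, `g_nap_scale`,
#'   `w_scale`.
#' @param clamps List of clamp events, each
#'   `list(trigger = "time"|"burst_init", at = ms, action = ...)` with
#'   action one of `syn_off`, `freeze_mnap_nonspiked`, `freeze_hnap`,
#'   `freeze_d`, `freeze_hnap_d`.
#' @param g_tonic Optional override of the per-neuron tonic drive (nS).
#' @returns A `sim_record`: spike raster, optional traces, event log.
#' @export
simulate_network <- function(network, config = simulation_config(),
                             schedule = list(), clamps = list(),
                             g_tonic = NULL) {
  stopifnot(inherits(network, "prebotc_network"))
  neurons <- network$neurons
  if (!is.null(g_tonic)) neurons$g_tonic <- rep_len(g_tonic, nrow(neurons))
  run_engine(cond_matrix(neurons), network$kinetics, network$env,
             network$w, network$dyn, config, schedule, clamps,
             c_m = neurons$c_m[1])
}

#' Simulate a single uncoupled neuron
#'
#' @param params A [neuron_parameters()] object.
#' @param env An [ion_environment()].
#' @param config A [simulation_config()]; trace recording defaults to the
#'   neuron's membrane potential at full resolution if `record_dt > 0`.
#' @param g_tonic Optional tonic-drive override (nS).
#' @inheritParams simulate_network
#' @returns A `sim_record`.
#' @export
simulate_neuron <- function(params, env = ion_environment(),
                            config = simulation_config(),
                            schedule = list(), clamps = list(),
                            g_tonic = NULL) {
  stopifnot(inherits(params, "neuron_params"))
  if (config$record_dt > 0 && length(config$record_neurons) == 0)
    config$record_neurons <- 1L
  cond <- matrix(c(params$g_na, params$g_k, params$g_spk, params$g_ahp,
                   params$g_nap, params$g_ca, params$g_leak,
                   if (is.null(g_tonic)) params$g_tonic else g_tonic),
                 nrow = 1)
  run_engine(cond, params$kinetics, env, NULL, synapse_dynamics(), config,
             schedule, clamps, c_m = params$c_m)
}

# batch of uncoupled neurons sharing kinetics/env; cond is an n x 8 matrix
simulate_uncoupled <- function(cond, kinetics, env, config,
                               schedule = list(), c_m = 36) {
  run_engine(cond, kinetics, env, NULL, synapse_dynamics(), config,
             schedule, list(), c_m = c_m)
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record> ", x$n, " neuron(s), ", x$duration, " ms, dt = ",
      x$dt, " ms, ", nrow(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' Tidy a simulation record into its spike raster
#'
#' @param x A `sim_record`.
#' @param ... Unused.
#' @returns A tibble with columns `neuron`, `time` (ms).
#' @export
tidy.sim_record <- function(x, ...) x$spikes

#' One-row summary of a simulation record
#'
#' @param x A `sim_record`.
#' @param ... Unused.
#' @export
glance.sim_record <- function(x, ...) {
  tibble::tibble(
    n_neurons = x$n, duration = x$duration, dt = x$dt,
    n_spikes = nrow(x$spikes),
    mean_rate = nrow(x$spikes) / x$n / (x$duration / 1000)
  )
}

#' Detect burst initiation from the network-mean persistent-sodium
#' inactivation gate
#'
#' Burst initiation is defined as the peak of the recovery of the mean
#' `h_NaP` during the inter-burst interval: the trace is smoothed with a
#' moving average and the first interior local maximum after `arm_after`
#' is returned.
#'
#' @param time Time points (ms), uniformly spaced.
#' @param h_mean Network-mean `h_NaP` at those times.
#' @param smooth_ms Moving-average window (ms).
#' @param arm_after Ignore maxima before this time (ms).
#' @returns Trigger time (ms), or `NA` if no interior maximum exists.
#' @export
detect_burst_initiation <- function(time, h_mean, smooth_ms = 50,
                                    arm_after = 0) {
  stopifnot(length(time) == length(h_mean), length(time) > 2)
  dt <- time[2] - time[1]
  k <- max(1L, round(smooth_ms / dt))
  sm <- as.numeric(stats::filter(h_mean, rep(1 / k, k), sides = 1))
  sm[seq_len(k - 1)] <- cumsum(h_mean[seq_len(k - 1)]) / seq_len(k - 1)
  runmax <- -Inf
  for (i in seq_along(sm)) {
    if (time[i] < arm_after) next
    if (sm[i] > runmax) runmax <- sm[i]
    else if (is.finite(runmax) && sm[i] < runmax - 1e-5) return(time[i])
  }
  NA_real_
}
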
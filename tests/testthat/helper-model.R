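# shared fixtures and slow-but-transparent reference implementations

default_env <- ion_environment()

# pure-R forward Euler for a single uncoupled neuron; independent of the
# C++ engine (direct kinetics evaluation, no lookup tables)
euler_reference <- function(params, env = default_env, duration, dt = 0.025,
                            g_tonic = NULL, init_v = -60) {
  if (!is.null(g_tonic)) params$g_tonic <- g_tonic
  state <- neuron_state(params, env, v = init_v)
  gate_names <- setdiff(names(state), c("v", "d"))
  n_steps <- round(duration / dt)
  v_out <- numeric(n_steps + 1)
  v_out[1] <- state$v
  for (s in seq_len(n_steps)) {
    d <- membrane_derivative(state, params, env, g_syn = 0)
    state$v <- state$v + dt * d$dv
    for (nm in gate_names) {
      x <- state[[nm]] + dt * d$dgates[[nm]]
      state[[nm]] <- min(max(x, 0), 1)
    }
    v_out[s + 1] <- state$v
  }
  v_out
}

# simulate a network's neurons with no synapse matrix at all (engine's
# uncoupled path), for trajectory-identity checks against zero weights
run_engine_uncoupled_for_test <- function(net, cfg, g_tonic) {
  neurons <- net$neurons
  neurons$g_tonic <- g_tonic
  prebotc:::simulate_uncoupled(
    prebotc:::cond_matrix(neurons), net$kinetics, net$env, cfg,
    c_m = neurons$c_m[1]
  )
}

# expensive computations shared between acceptance tests, computed lazily
.acc_cache <- new.env(parent = emptyenv())
acc_get <- function(key, compute) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- compute()
  .acc_cache[[key]]
}

# burst-capable percentage of a sampled population, averaged over seeds
capable_percent <- function(seeds, env = default_env, g_spk_dist = c(0, 12),
                            kinetics = default_kinetics(), ...) {
  vals <- vapply(seeds, function(s) {
    pop <- sample_population(network_spec(n = 100, g_spk_dist = g_spk_dist,
                                          seed = s), env)
    cap <- population_capability(pop, env, kinetics, ...)
    100 * mean(cap$capable)
  }, numeric(1))
  mean(vals)
}
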
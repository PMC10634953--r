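#' Classify intrinsic burst capability of an uncoupled neuron
#'
#' Sweeps the tonic excitatory conductance over a grid and classifies the
#' steady-state activity at each point (silent, bursting, tonic).  A neuron
#' is burst-capable if any grid point yields bursting.  The sweep runs in
#' ascending order and, because activity in this model progresses
#' silent -> bursting -> tonic with increasing drive, it can stop early
#' once bursting is seen (capable) or once the neuron has gone tonic on
#' two consecutive points without ever bursting (incapable); two points
#' are required because directly at the bursting threshold the burst
#' period can exceed the analysis window.
#'
#' @param params A [neuron_parameters()] object (synapses absent).
#' @param env An [ion_environment()].
#' @param g_tonic_grid Drive grid (nS), sorted ascending.
#' @param transient Discarded settling window per point (ms).
#' @param window Analysis window per point (ms).
#' @param dt Integration step (ms).
#' @param early_stop Stop the sweep as soon as the label is decided.
#' @param chunk Grid points simulated per engine call.
#' @param refine_res Resolution (nS) of the bisection refinement applied
#'   to each silent-to-tonic boundary when no bursting point was found on
#'   the coarse grid: the bursting band of a marginal pacemaker can be
#'   narrower than the grid step.  `NULL` disables refinement.
#' @returns An object of class `capability_profile`: list with `capable`
#'   (logical) and `modes` (tibble `g_tonic`, `label` over evaluated
#'   points, refined points included).
#' @export
classify_burst_capability <- function(params, env = ion_environment(),
                                      g_tonic_grid = seq(0, 2, by = 0.05),
                                      transient = 10000, window = 30000,
                                      dt = 0.025, early_stop = TRUE,
                                      chunk = 6L, refine_res = 0.0125) {
  stopifnot(inherits(params, "neuron_params"), !is.unsorted(g_tonic_grid))
  cfg <- simulation_config(dt = dt, duration = transient + window,
                           transient = transient)
  base <- c(params$g_na, params$g_k, params$g_spk, params$g_ahp,
            params$g_nap, params$g_ca, params$g_leak, 0)
  classify_at <- function(gt) {
    cond <- matrix(rep(base, each = length(gt)), nrow = length(gt))
    cond[, 8] <- gt
    rec <- simulate_uncoupled(cond, params$kinetics, env, cfg,
                              c_m = params$c_m)
    vapply(seq_along(gt), function(q)
      classify_activity(rec$spikes$time[rec$spikes$neuron == q],
                        c(transient, transient + window)),
      character(1))
  }
  labels <- character(0)
  gts <- numeric(0)
  capable <- FALSE
  tonic_run <- 0L
  i <- 1L
  while (i <= length(g_tonic_grid)) {
    idx <- i:min(i + chunk - 1L, length(g_tonic_grid))
    labs <- classify_at(g_tonic_grid[idx])
    done <- FALSE
    for (q in seq_along(idx)) {
      lab <- labs[q]
      labels <- c(labels, lab)
      gts <- c(gts, g_tonic_grid[idx[q]])
      if (lab == "bursting") {
        capable <- TRUE
        if (early_stop) { done <- TRUE; break }
      }
      tonic_run <- if (lab == "tonic") tonic_run + 1L else 0L
      if (early_stop && tonic_run >= 2L) { done <- TRUE; break }
    }
    if (done && early_stop) break
    i <- idx[length(idx)] + 1L
  }
  # bisect each silent -> tonic boundary for a bursting band narrower
  # than the grid step
  if (!capable && !is.null(refine_res)) {
    bounds <- which(labels[-length(labels)] == "silent" &
                      labels[-1] == "tonic")
    for (b in bounds) {
      lo <- gts[b]; hi <- gts[b + 1]
      while (hi - lo > refine_res && !capable) {
        mid <- (lo + hi) / 2
        lab <- classify_at(mid)
        labels <- c(labels, lab)
        gts <- c(gts, mid)
        if (lab == "bursting") capable <- TRUE
        else if (lab == "silent") lo <- mid
        else hi <- mid
      }
      if (capable) break
    }
  }
  ord <- order(gts)
  structure(
    list(capable = capable,
         modes = tibble::tibble(g_tonic = gts[ord], label = labels[ord])),
    class = "capability_profile"
  )
}

#' @export
print.capability_profile <- function(x, ...) {
  cat("<capability_profile> ",
      if (x$capable) "burst-capable" else "burst-incapable",
      " (", nrow(x$modes), " grid points evaluated)\n", sep = "")
  invisible(x)
}

#' Is a neuron burst-capable?
#'
#' @param x A `capability_profile` or [neuron_parameters()] object (the
#'   latter is classified first).
#' @param ... Passed to [classify_burst_capability()] for raw parameters.
#' @returns Logical.
#' @export
is_burst_capable <- function(x, ...) {
  if (inherits(x, "capability_profile")) return(x$capable)
  classify_burst_capability(x, ...)$capable
}

#' Burst capability of every neuron in a sampled population
#'
#' Applies [classify_burst_capability()] to each row of a population table
#' (uncoupled, i.e. ignoring the connectome).
#'
#' @param neurons Population tibble as from [sample_population()] or a
#'   `prebotc_network` (its `neurons` table is used).
#' @param env,kinetics Shared environment and kinetics.
#' @param ... Passed to [classify_burst_capability()].
#' @returns The input tibble with a logical `capable` column.
#' @export
population_capability <- function(neurons, env = ion_environment(),
                                  kinetics = default_kinetics(), ...) {
  if (inherits(neurons, "prebotc_network")) {
    env <- neurons$env
    kinetics <- neurons$kinetics
    neurons <- neurons$neurons
  }
  caps <- purrr::map_lgl(seq_len(nrow(neurons)), function(i) {
    p <- neuron_parameters(
      g_spk = neurons$g_spk[i], g_ahp = neurons$g_ahp[i],
      g_nap = neurons$g_nap[i], g_leak = neurons$g_leak[i],
      kinetics = kinetics
    )
    classify_burst_capability(p, env, ...)$capable
  })
  dplyr::mutate(neurons, capable = caps)
}

#' Map burst capability over (g_NaP, g_Leak) space
#'
#' @param g_nap_grid,g_leak_grid Conductance grids (nS).
#' @param g_spk,g_ahp Spike-shape conductances applied uniformly.
#' @param env,kinetics Shared environment and kinetics.
#' @param ... Passed to [classify_burst_capability()].
#' @returns A tibble of class `capability_map` with columns `g_nap`,
#'   `g_leak`, `capable`.
#' @export
map_capability_region <- function(g_nap_grid, g_leak_grid, g_spk = 0,
                                  g_ahp = 0, env = ion_environment(),
                                  kinetics = default_kinetics(), ...) {
  grid <- tidyr::expand_grid(g_nap = g_nap_grid, g_leak = g_leak_grid)
  grid$g_spk <- g_spk
  grid$g_ahp <- g_ahp
  out <- population_capability(grid, env, kinetics, ...)
  class(out) <- c("capability_map", class(out))
  out
}

#' Smallest spike-shape conductance abolishing intrinsic bursting
#'
#' Bisects over `g_SPK` (or `g_AHP`) to find the smallest value at which
#' the neuron is burst-incapable at every level of tonic drive.
#'
#' @param params Baseline [neuron_parameters()] (typically the canonical
#'   burster).
#' @param which `"spk"` or `"ahp"`.
#' @param env An [ion_environment()].
#' @param lower,upper Bracketing conductances (nS); `lower` must leave the
#'   neuron capable and `upper` must not.
#' @param tol Bisection resolution (nS).
#' @param ... Passed to [classify_burst_capability()].
#' @returns Critical conductance (nS).
#' @export
critical_spike_conductance <- function(params, which = c("spk", "ahp"),
                                       env = ion_environment(),
                                       lower = 0, upper = 20, tol = 0.05,
                                       ...) {
  which <- match.arg(which)
  set_g <- function(p, g) {
    if (which == "spk") p$g_spk <- g else p$g_ahp <- g
    p
  }
  capable_at <- function(g)
    classify_burst_capability(set_g(params, g), env, ...)$capable
  if (!capable_at(lower))
    stop("neuron already burst-incapable at the lower bracket",
         call. = FALSE)
  while (capable_at(upper)) {
    lower <- upper
    upper <- upper * 2
    if (upper > 200) stop("no upper bracket found", call. = FALSE)
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (capable_at(mid)) lower <- mid else upper <- mid
  }
  upper
}

#' Attenuate the persistent sodium conductance in a subset of neurons
#'
#' Multiplies `g_NaP` of the selected neurons by `1 - fraction`.  Subset
#' membership ("initially burst-capable") is fixed at baseline: pass the
#' baseline capability flags, or they are computed on the unblocked
#' network.
#'
#' @param network A `prebotc_network`.
#' @param fraction Block fraction in `[0, 1]`.
#' @param subset `"all"`, `"capable"`, or `"incapable"`.
#' @param capability Logical vector of baseline burst capability (required
#'   for subset blocks unless it should be computed here).
#' @param ... Passed to [population_capability()] when capability must be
#'   computed.
#' @returns The modified network; attribute `remaining_g_nap_fraction`
#'   reports the network-total `g_NaP` relative to baseline.
#' @export
apply_inap_block <- function(network, fraction,
                             subset = c("all", "capable", "incapable"),
                             capability = NULL, ...) {
  stopifnot(inherits(network, "prebotc_network"))
  if (fraction < 0 || fraction > 1)
    stop("block fraction must be in [0, 1]", call. = FALSE)
  subset <- match.arg(subset)
  sel <- if (subset == "all") {
    rep(TRUE, nrow(network$neurons))
  } else {
    if (is.null(capability))
      capability <- population_capability(network, ...)$capable
    if (subset == "capable") capability else !capability
  }
  total0 <- sum(network$neurons$g_nap)
  network$neurons$g_nap[sel] <- network$neurons$g_nap[sel] * (1 - fraction)
  attr(network, "remaining_g_nap_fraction") <-
    sum(network$neurons$g_nap) / total0
  network
}

#' Hypoxia time course
#'
#' Acute hypoxia is modelled as two sequential logistic transitions: an
#' early hyperpolarizing shift of the fast-sodium (in)activation midpoints
#' followed by a slower accumulation of intracellular sodium.  Each
#' logistic is normalised so the output equals its baseline exactly at the
#' onset and baseline + amplitude asymptotically.
#'
#' @param onset Onset time (s); before it both outputs sit at baseline.
#' @param dv_amplitude,dv_midpoint,dv_steepness Midpoint-shift logistic:
#'   amplitude (mV), midpoint and steepness (s, relative to onset).
#' @param na_baseline,na_amplitude,na_midpoint,na_steepness Intracellular
#'   sodium logistic (mM and s).
#' @returns An object of class `hypoxia_schedule`.
#' @export
hypoxia_schedule <- function(onset = 0, dv_amplitude = -1,
                             dv_midpoint = 40, dv_steepness = 5,
                             na_baseline = 15, na_amplitude = 32.5,
                             na_midpoint = 70, na_steepness = 10) {
  stopifnot(na_baseline > 0, na_baseline + na_amplitude > 0)
  structure(
    list(onset = onset, dv_amplitude = dv_amplitude,
         dv_midpoint = dv_midpoint, dv_steepness = dv_steepness,
         na_baseline = na_baseline, na_amplitude = na_amplitude,
         na_midpoint = na_midpoint, na_steepness = na_steepness),
    class = "hypoxia_schedule"
  )
}

logistic01 <- function(t, mid, steep) {
  l <- function(x) 1 / (1 + exp(-(x - mid) / steep))
  pmax(0, (l(t) - l(0)) / (1 - l(0)))
}

#' Evaluate the hypoxia environment at a time point
#'
#' @param t Time (s), vectorised.
#' @param sched A [hypoxia_schedule()].
#' @returns A tibble with `t`, `dv_half_na` (mV), `na_in` (mM).
#' @export
hypoxia_environment <- function(t, sched = hypoxia_schedule()) {
  tr <- pmax(0, t - sched$onset)
  pre <- t < sched$onset
  dv <- sched$dv_amplitude *
    logistic01(tr, sched$dv_midpoint, sched$dv_steepness)
  na <- sched$na_baseline + sched$na_amplitude *
    logistic01(tr, sched$na_midpoint, sched$na_steepness)
  dv[pre] <- 0
  na[pre] <- sched$na_baseline
  tibble::tibble(t = t, dv_half_na = dv, na_in = na)
}

#' Convert a hypoxia schedule to engine schedules
#'
#' Samples the logistic time courses on a regular grid for the piecewise
#' linear schedule interface of [simulate_network()].
#'
#' @param sched A [hypoxia_schedule()].
#' @param duration Simulation length (ms).
#' @param step Sampling interval (ms).
#' @returns A named schedule list (`dv_half`, `na_in`).
#' @export
as_engine_schedule <- function(sched, duration, step = 100) {
  stopifnot(inherits(sched, "hypoxia_schedule"))
  tt <- seq(0, duration, by = step)
  hx <- hypoxia_environment(tt / 1000, sched)
  list(dv_half = list(time = tt, value = hx$dv_half_na),
       na_in = list(time = tt, value = hx$na_in))
}

#' Developmental scaling of conductance densities
#'
#' Multiplies all voltage-gated conductances (`g_Na`, `g_K`, `g_SPK`,
#' `g_AHP`, `g_Ca`) by `s`; the persistent sodium conductance co-scales as
#' `1 + m (s - 1)` so that every ratio `m` coincides with the unscaled
#' model at `s = 1`.  Leak and tonic conductances are untouched.
#'
#' @param x A [neuron_parameters()] or `prebotc_network`.
#' @param s Scaling factor (> 0) applied to voltage-gated conductances.
#' @param m Persistent-sodium co-scaling ratio (>= 0).
#' @returns Object of the same class with scaled conductances.
#' @export
development_scale <- function(x, s, m = 0) {
  stopifnot(s > 0, m >= 0)
  nap_fac <- 1 + m * (s - 1)
  if (nap_fac < 0) {
    warning("g_NaP scale clipped at 0 (m * (s - 1) < -1)", call. = FALSE)
    nap_fac <- 0
  }
  if (inherits(x, "neuron_params")) {
    x$g_na <- x$g_na * s; x$g_k <- x$g_k * s; x$g_spk <- x$g_spk * s
    x$g_ahp <- x$g_ahp * s; x$g_ca <- x$g_ca * s
    x$g_nap <- x$g_nap * nap_fac
  } else if (inherits(x, "prebotc_network")) {
    n <- x$neurons
    n$g_na <- n$g_na * s; n$g_k <- n$g_k * s; n$g_spk <- n$g_spk * s
    n$g_ahp <- n$g_ahp * s; n$g_ca <- n$g_ca * s
    n$g_nap <- n$g_nap * nap_fac
    x$neurons <- n
  } else stop("unsupported input", call. = FALSE)
  x
}

#' Temperature scaling of gating rates and capacitance
#'
#' All gating, synaptic and depression time constants are multiplied by
#' `Q10^(-(T - T_ref)/10)` (rates speed up when warm) and membrane
#' capacitance grows by 0.3% per degree C.
#'
#' @param temperature Temperature (degrees C), vectorised.
#' @param t_ref Reference temperature (degrees C).
#' @param q10 Temperature coefficient of the gating rates.
#' @param cap_ref Capacitance at the reference temperature (pF).
#' @returns A tibble with `temperature`, `tau_scale`, `capacitance`.
#' @export
temperature_scaling <- function(temperature, t_ref = 27, q10 = 1.5,
                                cap_ref = 36) {
  stopifnot(q10 > 0)
  tibble::tibble(
    temperature = temperature,
    tau_scale = q10^(-(temperature - t_ref) / 10),
    capacitance = cap_ref * 1.003^(temperature - t_ref)
  )
}

#' Rhythmicity of the coupled network across an excitability range
#'
#' Simulates the coupled network at each tonic-drive level and summarises
#' the population rhythm.
#'
#' @param network A `prebotc_network`.
#' @param g_tonic_grid Drive grid (nS).
#' @param transient Discarded settling window (ms).
#' @param window Analysis window (ms).
#' @param dt Integration step (ms).
#' @returns A tibble: `g_tonic`, `is_rhythmic`, `frequency`, `amplitude`,
#'   `n_peaks`.
#' @export
rhythmic_range <- function(network, g_tonic_grid, transient = 5000,
                           window = 30000, dt = 0.025) {
  cfg <- simulation_config(dt = dt, duration = transient + window,
                           transient = transient)
  purrr::map_dfr(g_tonic_grid, function(gt) {
    rec <- simulate_network(network, cfg, g_tonic = gt)
    rm <- rhythm_metrics(population_rate(rec))
    tibble::tibble(g_tonic = gt, is_rhythmic = rm$is_rhythmic,
                   frequency = rm$frequency, amplitude = rm$amplitude,
                   n_peaks = rm$n_peaks)
  })
}
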
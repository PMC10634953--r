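#' Detect spikes in a membrane-potential trace
#'
#' A spike is one upward crossing of the threshold, with a refractory
#' lockout suppressing re-crossings within the rising phase.
#'
#' @param v Membrane potential trace (mV), uniformly sampled.
#' @param dt Sampling interval (ms).
#' @param threshold Crossing threshold (mV).
#' @param refractory Lockout (ms).
#' @returns Spike times (ms, time of the first sample at/above threshold).
#' @export
detect_spikes <- function(v, dt, threshold = -35, refractory = 1) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  up <- which(v[-n] < threshold & v[-1] >= threshold)
  if (length(up) == 0) return(numeric(0))
  t <- up * dt
  keep <- rep(TRUE, length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (t[i] - last < refractory) keep[i] <- FALSE else last <- t[i]
  }
  t[keep]
}

#' Spike height and afterhyperpolarization of a steadily spiking neuron
#'
#' Quantifies spike shape under the standard protocol: the persistent
#' sodium conductance is removed (`g_NaP = 0`) so the neuron fires
#' tonically without bursting, it is driven to steady repetitive spiking by
#' a fixed tonic conductance, and the mean spike peak (height) and mean
#' inter-spike minimum (AHP trough) are taken over the last `n_spikes`
#' inter-spike intervals of the run.
#'
#' @param params A [neuron_parameters()]; `g_nap` is forced to 0.
#' @param env An [ion_environment()].
#' @param drive Tonic conductance used to elicit spiking (nS).  The default
#'   is the package's calibrated quantification drive.
#' @param duration Run length (ms).
#' @param n_spikes Number of terminal inter-spike intervals averaged.
#' @param dt Integration step (ms).
#' @returns A one-row tibble: `height` (mV, mean peak), `ahp` (mV, mean
#'   trough), `n_spikes` (total spikes observed), `rate` (Hz).
#' @export
spike_shape_metrics <- function(params, env = ion_environment(),
                                drive = quantification_drive(),
                                duration = 20000, n_spikes = 10,
                                dt = 0.025) {
  params$g_nap <- 0
  rec <- simulate_neuron(
    params, env,
    simulation_config(dt = dt, duration = duration, record_dt = dt),
    g_tonic = drive
  )
  st <- rec$spikes$time
  if (length(st) < n_spikes + 1)
    stop("neuron not spiking steadily at this drive (",
         length(st), " spikes)", call. = FALSE)
  v <- rec$traces[[paste0("v_", 1L)]]
  tt <- rec$traces$time
  m <- length(st)
  ks <- seq(m - n_spikes, m - 1)
  peaks <- ahps <- numeric(length(ks))
  for (q in seq_along(ks)) {
    k <- ks[q]
    seg <- v[tt >= st[k] & tt < st[k + 1]]
    peaks[q] <- max(seg)
    ahps[q] <- min(seg)
  }
  tibble::tibble(
    height = mean(peaks), ahp = mean(ahps), n_spikes = m,
    rate = 1000 / mean(diff(st[ks]))
  )
}

#' Classify an activity pattern as silent, bursting, or tonic
#'
#' Spikes inside the analysis window are grouped into clusters separated
#' by quiescent gaps longer than `max(300 ms, 5 x median ISI)`; the
#' adaptive term separates the two timescales of the model (intra-burst
#' intervals are much shorter than inter-burst intervals).  Fewer than
#' three spikes is silent; at least three clusters of two or more spikes is
#' bursting; anything else is tonic.
#'
#' @param spike_times Spike times (ms).
#' @param window Length-2 analysis window (ms); spikes outside are ignored.
#' @param min_gap Floor of the cluster-separating gap (ms).
#' @param min_clusters Clusters (of >= 2 spikes) required for "bursting".
#' @returns One of `"silent"`, `"bursting"`, `"tonic"`.
#' @export
classify_activity <- function(spike_times, window = NULL, min_gap = 300,
                              min_clusters = 3) {
  st <- sort(spike_times)
  if (!is.null(window)) st <- st[st >= window[1] & st <= window[2]]
  if (length(st) < 3) return("silent")
  isi <- diff(st)
  gap <- max(min_gap, 5 * median(isi))
  cluster <- cumsum(c(0, isi > gap))
  sizes <- tabulate(cluster + 1L)
  if (sum(sizes >= 2) >= min_clusters && any(isi > gap)) "bursting"
  else "tonic"
}

#' Population firing-rate histogram
#'
#' Action potentials per bin per neuron, in Hz:
#' `rate = count / (N * bin / 1000)`.
#'
#' @param spikes Spike raster: a tibble/data.frame with a `time` column
#'   (ms), or a `sim_record`.
#' @param n Number of neurons in the population.
#' @param bin Bin width (ms).
#' @param t_range Length-2 time range (ms); defaults to the raster span
#'   rounded to whole bins.
#' @returns A tibble with `time` (bin centre, ms) and `rate` (Hz).
#' @export
population_rate <- function(spikes, n = NULL, bin = 20, t_range = NULL) {
  if (inherits(spikes, "sim_record")) {
    if (is.null(n)) n <- spikes$n
    if (is.null(t_range)) t_range <- c(spikes$transient, spikes$duration)
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(n))
  st <- spikes$time
  if (is.null(t_range)) {
    t_range <- if (length(st)) c(0, max(st)) else c(0, bin)
  }
  edges <- seq(t_range[1], t_range[2] + bin - 1e-9, by = bin)
  if (length(edges) < 2) edges <- c(t_range[1], t_range[1] + bin)
  st <- st[st >= edges[1] & st < edges[length(edges)]]
  counts <- if (length(st) == 0) rep(0L, length(edges) - 1)
            else tabulate(findInterval(st, edges), nbins = length(edges) - 1)
  tibble::tibble(
    time = edges[-length(edges)] + bin / 2,
    rate = counts / (n * bin / 1000)
  )
}

# local maxima above a height and prominence floor, with a minimum
# separation (largest peak wins inside a conflict window)
find_rate_peaks <- function(time, rate, height_min, prom_min, min_sep) {
  n <- length(rate)
  if (n < 3) return(integer(0))
  cand <- which(rate[2:(n - 1)] >= rate[1:(n - 2)] &
                rate[2:(n - 1)] >= rate[3:n]) + 1L
  cand <- cand[rate[cand] >= height_min]
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(rate[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(time[i] - time[kept]) >= min_sep)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # prominence: drop to the higher of the two cols separating the peak
  # from its neighbours (or the trace edges)
  ok <- vapply(seq_along(kept), function(q) {
    i <- kept[q]
    left <- if (q == 1) 1L else kept[q - 1]
    right <- if (q == length(kept)) n else kept[q + 1]
    col <- max(min(rate[left:i]), min(rate[i:right]))
    (rate[i] - col) >= prom_min
  }, logical(1))
  kept[ok]
}

#' Rhythm metrics from a population rate trace
#'
#' Burst peaks are local maxima of the (lightly smoothed) rate trace that
#' exceed 20% of its 95th percentile in both height and prominence and are
#' separated by at least `min_sep`.  Frequency is the mean inverse
#' interpeak interval; amplitude is the mean peak rate.  Burst duration,
#' rise and decay are measured at half maximum of the cycle-triggered
#' average above its inter-burst baseline.  The trace is called rhythmic
#' when there are at least `min_peaks` peaks, the interpeak-interval
#' coefficient of variation is below `cv_max`, and the mean peak
#' prominence exceeds `noise_mult` times the trace's own high-frequency
#' noise (estimated from first differences of the raw trace) — a noise
#' floor that rejects the counting fluctuations of an asynchronous tonic
#' population without discarding genuinely weak collective rhythms.
#'
#' @param rate A tibble from [population_rate()] (columns `time`, `rate`).
#' @param min_sep Minimum interpeak separation (ms).
#' @param min_peaks Minimum number of peaks for rhythmicity.
#' @param cv_max Maximum interpeak-interval coefficient of variation.
#' @param smooth_bins Moving-average width (bins) applied before peak
#'   finding.
#' @param noise_mult Multiple of the high-frequency noise scale that the
#'   mean peak prominence must exceed for the trace to count as rhythmic.
#' @returns An object of class `rhythm_metrics` (a list); use [glance()]
#'   for a one-row summary or `$peaks` for peak times.
#' @export
rhythm_metrics <- function(rate, min_sep = 200, min_peaks = 5,
                           cv_max = 0.5, smooth_bins = 3, noise_mult = 4) {
  stopifnot(all(c("time", "rate") %in% names(rate)))
  tt <- rate$time
  r0 <- rate$rate
  k <- max(1L, smooth_bins)
  r <- as.numeric(stats::filter(r0, rep(1 / k, k), sides = 2))
  r[is.na(r)] <- r0[is.na(r)]
  thr <- 0.2 * quantile(r, 0.95, names = FALSE)
  pk <- find_rate_peaks(tt, r, max(thr, 1e-9), max(thr, 1e-9), min_sep)
  peaks <- tt[pk]
  ipi <- diff(peaks)
  freq <- if (length(ipi)) mean(1000 / ipi) else NA_real_
  amp <- if (length(pk)) mean(r0[pk]) else NA_real_

  # bin-to-bin counting noise of the raw trace; smoothing reduces it by
  # sqrt(k).  Peak prominences must clear this floor.
  sigma_hf <- sd(diff(r0)) / sqrt(2) / sqrt(k)
  prom <- if (length(pk) >= 2) {
    vapply(seq_along(pk), function(q) {
      left <- if (q == 1) 1L else pk[q - 1]
      right <- if (q == length(pk)) length(r) else pk[q + 1]
      r[pk[q]] - max(min(r[left:pk[q]]), min(r[pk[q]:right]))
    }, numeric(1))
  } else numeric(0)
  above_noise <- length(prom) > 0 &&
    (!is.finite(sigma_hf) || sigma_hf == 0 ||
       mean(prom) > noise_mult * sigma_hf)

  is_rhythmic <- length(peaks) >= min_peaks &&
    length(ipi) > 0 && sd(ipi) / mean(ipi) < cv_max && above_noise

  dur <- rise <- decay <- NA_real_
  cta <- NULL
  if (length(pk) >= 3) {
    bin <- tt[2] - tt[1]
    half_cycle <- floor(median(ipi) / 2 / bin)
    use <- pk[pk - half_cycle >= 1 & pk + half_cycle <= length(r)]
    if (length(use) >= 2 && half_cycle >= 2) {
      mat <- vapply(use, function(i) r[(i - half_cycle):(i + half_cycle)],
                    numeric(2 * half_cycle + 1))
      avg <- rowMeans(mat)
      lag <- (seq_along(avg) - half_cycle - 1) * bin
      cta <- tibble::tibble(lag = lag, rate = avg)
      base <- min(avg)
      half <- base + (max(avg) - base) / 2
      ic <- which.max(avg)
      above <- avg >= half
      i0 <- ic; while (i0 > 1 && above[i0 - 1]) i0 <- i0 - 1
      i1 <- ic; while (i1 < length(avg) && above[i1 + 1]) i1 <- i1 + 1
      rise <- (ic - i0) * bin
      decay <- (i1 - ic) * bin
      dur <- rise + decay
    }
  }

  structure(
    list(peaks = peaks, frequency = freq, amplitude = amp,
         duration = dur, rise = rise, decay = decay,
         is_rhythmic = is_rhythmic, n_peaks = length(peaks),
         ipi_cv = if (length(ipi) > 1) sd(ipi) / mean(ipi) else NA_real_,
         cta = cta),
    class = "rhythm_metrics"
  )
}

#' @export
print.rhythm_metrics <- function(x, ...) {
  cat("<rhythm_metrics> ", x$n_peaks, " peaks; ",
      if (x$is_rhythmic) "rhythmic" else "not rhythmic", sep = "")
  if (is.finite(x$frequency))
    cat(sprintf("; f = %.3f Hz, amplitude = %.1f Hz", x$frequency,
                x$amplitude))
  cat("\n")
  invisible(x)
}

#' @rdname rhythm_metrics
#' @param x A `rhythm_metrics` object.
#' @param ... Unused.
#' @export
glance.rhythm_metrics <- function(x, ...) {
  tibble::tibble(
    is_rhythmic = x$is_rhythmic, n_peaks = x$n_peaks,
    frequency = x$frequency, amplitude = x$amplitude,
    duration = x$duration, rise = x$rise, decay = x$decay,
    ipi_cv = x$ipi_cv
  )
}

#' Fraction of the population spiking between bursts
#'
#' For each cycle between consecutive burst peaks, counts the fraction of
#' neurons with at least one spike in the window starting `offset` after
#' one peak and ending `offset` after the next; when the burst duration
#' exceeds `offset` the window start is pushed to the burst end so that
#' intra-burst spikes are not counted.
#'
#' @param spikes Spike raster tibble (`neuron`, `time`) or `sim_record`.
#' @param peaks Burst peak times (ms), at least two.
#' @param n Number of neurons.
#' @param offset Window offset after each peak (ms).
#' @param burst_duration Optional burst duration (ms) used to extend the
#'   window start beyond `offset`.
#' @returns A tibble with one row per cycle: `cycle`, `t0`, `t1`,
#'   `fraction`.
#' @export
preinspiratory_fraction <- function(spikes, peaks, n = NULL, offset = 500,
                                    burst_duration = NULL) {
  if (inherits(spikes, "sim_record")) {
    if (is.null(n)) n <- spikes$n
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(n))
  if (length(peaks) < 2)
    stop("need at least two burst peaks", call. = FALSE)
  start_off <- max(offset, burst_duration %||% 0)
  purrr::map_dfr(seq_len(length(peaks) - 1), function(k) {
    t0 <- peaks[k] + start_off
    t1 <- peaks[k + 1] + offset
    act <- spikes$neuron[spikes$time >= t0 & spikes$time <= t1]
    tibble::tibble(cycle = k, t0 = t0, t1 = t1,
                   fraction = length(unique(act)) / n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
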
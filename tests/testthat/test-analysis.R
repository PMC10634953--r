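test_that("spike detection counts upward threshold crossings once", {
  dt <- 0.1
  expect_length(detect_spikes(rep(-60, 1000), dt), 0)
  # triangle wave crossing -35 mV upward three times
  tri <- rep(c(seq(-60, -20, length.out = 100),
               seq(-20, -60, length.out = 100)), 3)
  expect_length(detect_spikes(tri, dt), 3)
  # refractory lockout suppresses immediate re-crossings
  jitter <- c(seq(-60, -34, length.out = 50), -36, -34, -36,
              seq(-36, -60, length.out = 50))
  expect_length(detect_spikes(jitter, dt, refractory = 1), 1)
})

test_that("spike detection agrees with an independent peak-finding oracle", {
  p <- neuron_parameters(g_nap = 0)
  rec <- simulate_neuron(p, config = simulation_config(duration = 3000,
                                                       record_dt = 0.025),
                         g_tonic = 0.6)
  v <- rec$traces$v_1
  st <- detect_spikes(v, 0.025)
  # oracle: count local maxima above the threshold
  pk <- which(diff(sign(diff(v))) == -2) + 1
  n_oracle <- sum(v[pk] > -35)
  expect_equal(length(st), n_oracle)
  expect_equal(length(st), nrow(rec$spikes))
})

test_that("activity classification separates silent, tonic and bursting trains", {
  expect_equal(classify_activity(numeric(0)), "silent")
  expect_equal(classify_activity(c(100, 5000)), "silent")
  # perfectly periodic: no gap structure
  expect_equal(classify_activity(seq(0, 30000, by = 100)), "tonic")
  expect_equal(classify_activity(seq(0, 30000, by = 1000)), "tonic")
  # bursts: clusters of short intervals separated by long gaps
  burst <- function(t0) t0 + seq(0, 100, by = 20)
  train <- c(burst(0), burst(2500), burst(5000), burst(7500))
  expect_equal(classify_activity(train), "bursting")
  # two bursts are not enough
  expect_equal(classify_activity(c(burst(0), burst(2500))), "tonic")
  # label is invariant under time translation
  expect_equal(classify_activity(train + 12345), "bursting")
  # windowing drops outside spikes
  expect_equal(classify_activity(train, window = c(200, 2400)), "silent")
})

test_that("population rate has the right units and conserves spike counts", {
  empty <- population_rate(tibble::tibble(neuron = integer(0),
                                          time = numeric(0)),
                           n = 10, t_range = c(0, 1000))
  expect_true(all(empty$rate == 0))

  # 100 neurons spiking once inside a single 20 ms bin -> 50 Hz
  r <- population_rate(tibble::tibble(neuron = 1:100,
                                      time = runif(100, 40, 59.9)),
                       n = 100, bin = 20, t_range = c(0, 200))
  expect_equal(max(r$rate), 50)
  expect_equal(r$rate[r$time == 50], 50)

  # conservation for a random raster
  set.seed(42)
  rast <- tibble::tibble(neuron = sample(1:20, 500, TRUE),
                         time = runif(500, 0, 10000))
  r2 <- population_rate(rast, n = 20, bin = 20, t_range = c(0, 10000))
  expect_equal(sum(r2$rate) * 0.02 * 20, 500)
})

test_that("rhythm metrics recover the frequency and width of synthetic bursts", {
  tt <- seq(10, 40000, by = 20)
  centers <- seq(2000, 38000, by = 2000) # 0.5 Hz
  rate <- rowSums(vapply(centers,
                         function(c0) 30 * exp(-(tt - c0)^2 / (2 * 100^2)),
                         numeric(length(tt))))
  rm <- rhythm_metrics(tibble::tibble(time = tt, rate = rate))
  expect_true(rm$is_rhythmic)
  expect_equal(rm$frequency, 0.5, tolerance = 0.02)
  expect_equal(length(rm$peaks), length(centers) - 2, tolerance = 2)
  # duration at half maximum ~ Gaussian FWHM = 235 ms (one bin slack)
  expect_equal(rm$duration, 235, tolerance = 0.2)

  # flat trace: no rhythm
  flat <- rhythm_metrics(tibble::tibble(time = tt, rate = rep(5, length(tt))))
  expect_false(flat$is_rhythmic)

  # asynchronous tonic population (Poisson-count noise around a flat
  # mean) must not be called rhythmic
  set.seed(1)
  noisy <- rhythm_metrics(tibble::tibble(time = tt,
                                         rate = rpois(length(tt), 40) / 2))
  expect_false(noisy$is_rhythmic)
})

test_that("pre-inspiratory participation counts neurons active between bursts", {
  peaks <- c(1000, 3000, 5000)
  # neurons 1..4 spike mid-cycle, neuron 5 only inside the burst window
  rast <- tibble::tibble(
    neuron = c(1, 2, 3, 4, 5),
    time = c(2000, 2200, 2400, 3400, 1100)
  )
  pf <- preinspiratory_fraction(rast, peaks, n = 10)
  expect_equal(nrow(pf), 2)
  expect_equal(pf$fraction[1], 0.4) # neurons 1-4 in (1500, 3500]
  expect_true(all(pf$fraction >= 0 & pf$fraction <= 1))
  # every neuron spiking everywhere gives 1
  dense <- tidyr::expand_grid(neuron = 1:10, time = seq(0, 6000, by = 50))
  expect_true(all(preinspiratory_fraction(dense, peaks, n = 10)$fraction == 1))
  # long bursts push the window start beyond the 500 ms offset
  pf2 <- preinspiratory_fraction(rast, peaks, n = 10, burst_duration = 900)
  expect_equal(pf2$t0[1], 1900)
  expect_error(preinspiratory_fraction(rast, peaks[1], n = 10), "two")
})
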
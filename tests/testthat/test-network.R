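test_that("population sampling reproduces the bivariate conductance model", {
  spec <- network_spec(n = 10000, seed = 7)
  pop <- sample_population(spec)
  expect_equal(mean(pop$g_nap), 3.33, tolerance = 0.02)
  expect_equal(sd(pop$g_nap), 0.75, tolerance = 0.02)
  expect_equal(mean(pop$g_leak), 3.50113, tolerance = 0.01)
  expect_equal(cor(pop$g_nap, pop$g_leak), 0.8, tolerance = 0.02)
  expect_true(all(pop$g_nap >= 0 & pop$g_leak >= 0))

  # conditional s.d. shrinks by sqrt(1 - rho^2); with rho = 0 the
  # conditional mean is flat in g_NaP
  spec0 <- network_spec(n = 10000, rho = 0, seed = 7)
  pop0 <- sample_population(spec0)
  expect_lt(abs(cor(pop0$g_nap, pop0$g_leak)), 0.03)
  resid_sd <- sd(residuals(lm(g_leak ~ g_nap, data = pop)))
  expect_equal(resid_sd, 0.6 * 0.05 * 3.50113, tolerance = 0.01)
})

test_that("population sampling is reproducible and responds to K_bath", {
  a <- sample_population(network_spec(n = 50, seed = 3))
  b <- sample_population(network_spec(n = 50, seed = 3))
  expect_identical(a, b)
  lo <- sample_population(network_spec(n = 2000, seed = 3),
                          ion_environment(k_bath = 4))
  expect_equal(mean(lo$g_leak), mu_leak(4), tolerance = 0.02)
})

test_that("connectome sampling matches the directed Bernoulli model", {
  expect_equal(sum(sample_connectome(network_spec(n = 20, p_syn = 0,
                                                  seed = 1))$c_mat), 0)
  full <- sample_connectome(network_spec(n = 3, p_syn = 1, seed = 1))
  expect_equal(sum(full$c_mat), 6) # complete digraph minus diagonal
  expect_true(all(diag(full$c_mat) == 0))

  counts <- vapply(1:20, function(s) {
    con <- sample_connectome(network_spec(n = 100, p_syn = 0.13, seed = s))
    sum(con$c_mat)
  }, numeric(1))
  expected <- 9900 * 0.13
  sd_bin <- sqrt(9900 * 0.13 * 0.87)
  expect_true(all(abs(counts - expected) < 3 * sd_bin))
  con <- sample_connectome(network_spec(n = 100, seed = 5))
  expect_true(all(con$w >= 0 & con$w <= 0.2))
  expect_true(all(con$w[con$c_mat == 0] == 0))
})

test_that("depression follows the per-spike map and its periodic fixed point", {
  dyn <- synapse_dynamics()
  # one spike from the ceiling: multiplicative 20% depression
  expect_equal(depression_step(1, TRUE, 0, dyn), 0.8)
  # recovery toward the ceiling without spikes
  d <- 0.5
  for (i in 1:(8000 / 0.5)) d <- depression_step(d, FALSE, 0.5, dyn)
  expect_equal(d, 1, tolerance = 1e-3)

  # periodic spiking: simulated pre-spike value converges to the
  # closed-form fixed point
  for (t_isi in c(100, 250, 1000)) {
    d <- 1; dt <- 0.05
    pre <- NA
    for (spike in 1:40) {
      for (s in seq_len(t_isi / dt)) d <- depression_step(d, FALSE, dt, dyn)
      pre <- d
      d <- d * (1 - dyn$alpha_d)
    }
    expect_equal(pre, depression_fixed_point(t_isi, dyn), tolerance = 2e-3)
  }
})

test_that("aggregated synaptic drive decays exponentially and sums linearly", {
  dyn <- synapse_dynamics(tau_syn = 5)
  w <- matrix(0.2, 3, 3); diag(w) <- 0
  drive <- c(1, 0, 0)
  for (s in 1:200) drive <- synaptic_conductance_step(drive, logical(3),
                                                      rep(1, 3), w, 0.025, dyn)
  expect_equal(drive[1], exp(-1), tolerance = 1e-3) # 5 ms at tau = 5 ms
  # one spike adds W * D to each target instantaneously
  d2 <- synaptic_conductance_step(rep(0, 3), c(TRUE, FALSE, FALSE),
                                  c(0.5, 1, 1), w, 0.025, dyn)
  expect_equal(d2, c(0, 0.1, 0.1))
  # simultaneous spikes superpose
  d3 <- synaptic_conductance_step(rep(0, 3), c(TRUE, TRUE, FALSE),
                                  rep(1, 3), w, 0.025, dyn)
  expect_equal(d3, c(0.2, 0.2, 0.4))
})

test_that("network realizations are seed-deterministic", {
  n1 <- build_network(network_spec(n = 30, seed = 11))
  n2 <- build_network(network_spec(n = 30, seed = 11))
  expect_identical(n1$neurons, n2$neurons)
  expect_identical(n1$w, n2$w)
  n3 <- build_network(network_spec(n = 30, seed = 12))
  expect_false(identical(n1$w, n3$w))
})
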
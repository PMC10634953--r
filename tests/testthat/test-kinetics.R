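test_that("steady state is half-maximal at the midpoint and shifts translate it", {
  nap_m <- gate_kinetics(-47.1, 3.1, 1.0, -47.1, 6.2)
  expect_equal(steady_state(nap_m, -47.1), 0.5)
  # generic midpoint property for a spread of kinetics
  for (xh in c(-70, -40, 0)) for (k in c(-9, 4)) {
    kin <- gate_kinetics(xh, k, 2, xh, 10)
    expect_equal(steady_state(kin, xh), 0.5)
    expect_equal(steady_state(kin, xh + 3, shift = 3), 0.5)
  }
})

test_that("steady state is monotone with direction set by the slope sign", {
  v <- seq(-100, 20, by = 0.5)
  act <- steady_state(gate_kinetics(-47.1, 3.1, 1, -47.1, 6.2), v)
  inact <- steady_state(gate_kinetics(-60, -9, 5000, -60, 9), v)
  expect_true(all(diff(act) > 0))
  expect_true(all(diff(inact) < 0))
  expect_true(all(act > 0 & act < 1))
  # inactivation saturates toward 1 when strongly hyperpolarized
  expect_gt(steady_state(gate_kinetics(-60, -9, 5000, -60, 9), -120), 0.998)
})

test_that("time constant peaks at tau_half with value tau_max and is symmetric", {
  h_nap <- gate_kinetics(-60, -9, 5000, -60, 9)
  expect_equal(time_constant(h_nap, -60), 5000)
  for (d in c(1, 5, 20)) {
    expect_equal(time_constant(h_nap, -60 + d), time_constant(h_nap, -60 - d))
  }
  v <- seq(-120, 20, by = 1)
  tau <- time_constant(h_nap, v)
  expect_true(all(tau > 0 & tau <= 5000))
  expect_equal(v[which.max(tau)], -60)
  # a shift moves the peak
  expect_equal(time_constant(h_nap, -55, shift = 5), 5000)
})

test_that("rectifier rates match direct evaluation and the singular limit", {
  kin <- rectifier_kinetics(0.011, 44, 5, 0.17, 49, 40)
  # direct evaluation away from the singularity (frozen oracle value)
  expect_equal(rectifier_activation(kin, 0)$alpha, 0.484073, tolerance = 1e-5)
  # removable singularity at V = -B_alpha: continuous to the analytic limit
  at <- rectifier_activation(kin, -44)$alpha
  expect_equal(at, 0.011 * 5, tolerance = 1e-9)
  near <- rectifier_activation(kin, -44 + c(-1e-6, 1e-6))$alpha
  expect_true(all(abs(near - at) < 1e-6))
  # normalization
  v <- seq(-90, 30, by = 2.5)
  ra <- rectifier_activation(kin, v)
  expect_true(all(ra$m_inf > 0 & ra$m_inf < 1))
  expect_equal(ra$m_inf, ra$alpha * ra$tau)
})

test_that("reversal potentials follow the Nernst/GHK-style formulas", {
  rv <- reversal_potentials(ion_environment())
  expect_equal(rv$e_na, 55.1884, tolerance = 1e-4)
  expect_equal(rv$e_leak, -63.7310, tolerance = 1e-4)
  # K reversal vanishes when bath matches intracellular potassium
  rv0 <- reversal_potentials(ion_environment(k_bath = 125))
  expect_equal(rv0$e_k, 0)
  expect_error(ion_environment(na_in = -1), "positive")
})

test_that("membrane derivative obeys zero-current and fixed-point identities", {
  env <- ion_environment()
  rv <- reversal_potentials(env)
  kin <- default_kinetics()

  p0 <- neuron_parameters(g_na = 0, g_k = 0, g_spk = 0, g_ahp = 0,
                          g_nap = 0, g_leak = 0, kinetics = kin)
  st <- neuron_state(p0, env, v = -50)
  expect_equal(membrane_derivative(st, p0, env)$dv, 0)

  # zero driving force: sodium current vanishes at E_Na
  p1 <- neuron_parameters(g_na = 150, g_k = 0, g_nap = 0, g_leak = 0,
                          kinetics = kin)
  st1 <- neuron_state(p1, env, v = rv$e_na)
  expect_equal(unname(membrane_derivative(st1, p1, env)$currents["i_na"]), 0)

  # leak-only neuron relaxes to E_Leak
  p2 <- neuron_parameters(g_na = 0, g_k = 0, g_nap = 0, g_leak = 3.5,
                          kinetics = kin)
  st2 <- neuron_state(p2, env, v = -40)
  expect_gt(membrane_derivative(st2, p2, env)$dv * (rv$e_leak - (-40)), 0)
  v <- euler_reference(p2, env, duration = 2000, g_tonic = 0)
  expect_equal(tail(v, 1), rv$e_leak, tolerance = 1e-3)

  # currents are linear in their maximal conductance at fixed state
  pa <- neuron_parameters(kinetics = kin)
  pb <- pa; pb$g_na <- 2 * pa$g_na; pb$g_nap <- 2 * pa$g_nap
  sta <- neuron_state(pa, env, v = -45)
  ca <- membrane_derivative(sta, pa, env)$currents
  cb <- membrane_derivative(sta, pb, env)$currents
  expect_equal(unname(cb["i_na"]), unname(2 * ca["i_na"]))
  expect_equal(unname(cb["i_nap"]), unname(2 * ca["i_nap"]))
})

test_that("constructor invariants are enforced", {
  expect_error(gate_kinetics(-40, 5, -1, -40, 10))
  expect_error(neuron_parameters(g_na = -5), "nonnegative")
  expect_error(network_spec(p_syn = 1.3), "p_syn")
  expect_error(network_spec(rho = 1), "rho")
})
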
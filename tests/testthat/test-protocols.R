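test_that("persistent-sodium block scales the selected subset and composes", {
  net <- build_network(network_spec(n = 20, seed = 6))
  # identity at zero fraction
  b0 <- apply_inap_block(net, 0)
  expect_equal(b0$neurons$g_nap, net$neurons$g_nap)
  expect_equal(attr(b0, "remaining_g_nap_fraction"), 1)
  # full block of all neurons removes everything
  b1 <- apply_inap_block(net, 1)
  expect_true(all(b1$neurons$g_nap == 0))
  # sequential blocks compose multiplicatively
  b2 <- apply_inap_block(apply_inap_block(net, 0.3), 0.5)
  b3 <- apply_inap_block(net, 1 - 0.7 * 0.5)
  expect_equal(b2$neurons$g_nap, b3$neurons$g_nap)
  # subset block with precomputed membership only touches the subset
  capability <- net$neurons$g_nap > median(net$neurons$g_nap)
  bs <- apply_inap_block(net, 1, subset = "capable", capability = capability)
  expect_true(all(bs$neurons$g_nap[capability] == 0))
  expect_equal(bs$neurons$g_nap[!capability], net$neurons$g_nap[!capability])
  expect_equal(attr(bs, "remaining_g_nap_fraction"),
               sum(net$neurons$g_nap[!capability]) / sum(net$neurons$g_nap))
  expect_error(apply_inap_block(net, 1.2), "fraction")
})

test_that("hypoxia time courses are anchored at baseline and asymptote", {
  s <- hypoxia_schedule()
  h0 <- hypoxia_environment(0, s)
  expect_equal(h0$dv_half_na, 0)
  expect_equal(h0$na_in, 15)
  hinf <- hypoxia_environment(1e6, s)
  expect_equal(hinf$dv_half_na, -1, tolerance = 1e-6)
  expect_equal(hinf$na_in, 47.5, tolerance = 1e-6)
  # logistic midpoint reaches about half the amplitude, and the midpoint
  # shift leads the sodium accumulation
  hm <- hypoxia_environment(40, s)
  expect_equal(hm$dv_half_na, -0.5, tolerance = 0.01)
  expect_lt(hypoxia_environment(40, s)$na_in - 15, 0.5 * 32.5)
  # onset delays everything
  s2 <- hypoxia_schedule(onset = 10)
  expect_equal(hypoxia_environment(9.9, s2)$na_in, 15)
  # monotone time courses
  hh <- hypoxia_environment(seq(0, 300, by = 1), s)
  expect_true(all(diff(hh$na_in) >= 0))
  expect_true(all(diff(hh$dv_half_na) <= 0))
})

test_that("developmental scaling multiplies the right conductances", {
  p <- neuron_parameters(g_spk = 4, g_ahp = 6)
  # control point: s = 1 is the identity for every co-scaling ratio
  for (m in c(0, 0.5, 1, 2)) {
    ps <- development_scale(p, s = 1, m = m)
    expect_equal(ps[c("g_na", "g_k", "g_spk", "g_ahp", "g_nap", "g_leak")],
                 p[c("g_na", "g_k", "g_spk", "g_ahp", "g_nap", "g_leak")])
  }
  # m = 0 doubles everything voltage-gated except g_NaP
  p2 <- development_scale(p, s = 2, m = 0)
  expect_equal(p2$g_na, 300); expect_equal(p2$g_k, 440)
  expect_equal(p2$g_spk, 8); expect_equal(p2$g_ahp, 12)
  expect_equal(p2$g_nap, p$g_nap)
  expect_equal(p2$g_leak, p$g_leak)
  # m = 1 halves g_NaP along with the rest at s = 0.5
  p3 <- development_scale(p, s = 0.5, m = 1)
  expect_equal(p3$g_nap, p$g_nap / 2)
  expect_equal(p3$g_na, 75)
  # negative implied scale clips to zero with a warning
  expect_warning(p4 <- development_scale(p, s = 0.25, m = 2), "clipped")
  expect_equal(p4$g_nap, 0)
  # networks scale the same way
  net <- build_network(network_spec(n = 5, seed = 1))
  ns <- development_scale(net, s = 2, m = 0)
  expect_equal(ns$neurons$g_na, rep(300, 5))
  expect_equal(ns$neurons$g_nap, net$neurons$g_nap)
})

test_that("temperature scaling follows Q10 and the capacitance drift", {
  t0 <- temperature_scaling(27)
  expect_equal(t0$tau_scale, 1)
  expect_equal(t0$capacitance, 36)
  t37 <- temperature_scaling(37)
  expect_equal(t37$tau_scale, 1 / 1.5, tolerance = 1e-9)
  expect_equal(t37$capacitance, 36 * 1.003^10, tolerance = 1e-9)
  # about one picofarad over the ten-degree span
  expect_equal(t37$capacitance - 36, 1, tolerance = 0.1)
})

test_that("engine temperature handling matches the scaling rule", {
  # a neuron simulated at 37 C behaves like one whose taus and capacitance
  # were rescaled by hand at the reference temperature
  p <- canonical_burster()
  env37 <- ion_environment(temperature = 37)
  rec <- simulate_neuron(p, env37, simulation_config(duration = 1000,
                                                     record_dt = 0.025),
                         g_tonic = 0.6)
  sc <- temperature_scaling(37)
  kin <- default_kinetics()
  for (nm in names(kin)) {
    k <- kin[[nm]]
    if (inherits(k, "gate_kinetics")) kin[[nm]]$tau_max <- k$tau_max * sc$tau_scale
  }
  # the delayed rectifier's rate constants scale inversely with tau
  kin$m_k <- rectifier_kinetics(0.011 / sc$tau_scale, 44, 5,
                                0.17 / sc$tau_scale, 49, 40)
  p2 <- neuron_parameters(c_m = sc$capacitance, kinetics = kin,
                          g_nap = p$g_nap, g_leak = p$g_leak)
  rec2 <- simulate_neuron(p2, ion_environment(),
                          simulation_config(duration = 1000,
                                            record_dt = 0.025),
                          g_tonic = 0.6)
  expect_equal(nrow(rec$spikes), nrow(rec2$spikes))
  expect_lt(max(abs(rec$traces$v_1 - rec2$traces$v_1)), 0.5)
})

test_that("burst-capability regions shrink as spike-shape conductances grow", {
  # coarse grid: capable set at higher g_SPK is nested in the lower one
  g_nap <- c(2, 3.33, 5)
  g_leak <- c(3, 3.5)
  m0 <- map_capability_region(g_nap, g_leak, g_spk = 0,
                              transient = 6000, window = 18000)
  m5 <- map_capability_region(g_nap, g_leak, g_spk = 5,
                              transient = 6000, window = 18000)
  m10 <- map_capability_region(g_nap, g_leak, g_spk = 10,
                               transient = 6000, window = 18000)
  expect_true(all(m5$capable <= m0$capable))
  expect_true(all(m10$capable <= m5$capable))
  # the average pacemaker is capable at baseline
  expect_true(m0$capable[m0$g_nap == 3.33 & m0$g_leak == 3.5])
  # zero persistent sodium cannot burst at any drive
  p0 <- neuron_parameters(g_nap = 0)
  prof <- classify_burst_capability(p0, g_tonic_grid = seq(0, 2, 0.1),
                                    transient = 6000, window = 18000)
  expect_false(prof$capable)
  expect_false("bursting" %in% prof$modes$label)
})
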
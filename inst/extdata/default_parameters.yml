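# Standard single-neuron and network parameter set (flat key-value).
# Conductances nS, capacitance pF, voltages mV, times ms, concentrations mM.
# The spike-shape current kinetics (m_spk_*, h_spk_half, m_ahp_*) are the
# package's calibrated values; see ?calibrate_spike_currents.
c_m: 36.0
g_na: 150.0
g_k: 220.0
g_spk: 0.0
g_ahp: 0.0
g_nap: 3.33
g_ca: 0.0
g_leak: 3.5011
g_tonic: 0.0
m_na_half: -43.8
m_na_k: 6.0
m_na_tau_max: 0.25
m_na_tau_half: -43.8
m_na_k_tau: 14.0
h_na_half: -67.5
h_na_k: -11.8
h_na_tau_max: 8.46
h_na_tau_half: -67.5
h_na_k_tau: 12.8
k_A_alpha: 0.011
k_B_alpha: 44.0
k_k_alpha: 5.0
k_A_beta: 0.17
k_B_beta: 49.0
k_k_beta: 40.0
m_spk_half: -30.0
m_spk_k: 2.75
m_spk_tau_max: 0.30625
m_spk_k_tau: 14.0
h_spk_half: -30.0
h_spk_k: -11.8
h_spk_tau_max: 8.46
h_spk_k_tau: 12.8
m_ahp_half: -25.0
m_ahp_k: 1.0
m_ahp_tau: 4.90625
m_nap_half: -47.1
m_nap_k: 3.1
m_nap_tau_max: 1.0
m_nap_tau_half: -47.1
m_nap_k_tau: 6.2
h_nap_half: -60.0
h_nap_k: -9.0
h_nap_tau_max: 5000.0
h_nap_tau_half: -60.0
h_nap_k_tau: 9.0
na_in: 15.0
na_out: 120.0
k_in: 125.0
k_bath: 8.5
p_na: 1.0
p_k: 42.0
e_syn: 0.0
temperature: 27.0
t_ref: 27.0
q10: 1.5
mu_nap: 3.33
sigma_nap: 0.75
rho: 0.8
sigma_leak_frac: 0.05
p_syn: 0.13
w_max: 0.2
tau_syn: 5.0
d0: 1.0
tau_d: 1000.0
alpha_d: 0.2
quantification_drive: 0.4
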
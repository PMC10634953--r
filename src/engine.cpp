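// Fixed-step (forward Euler) integration engine for conductance-based
// preBotC model networks.  All gating kinetics are pre-tabulated on a fine
// voltage grid once per run; time-varying environments (hypoxia, K_bath,
// temperature) enter through cheap per-step scalars and a voltage-shift
// applied at lookup time, so the tables never need rebuilding mid-run.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

const double V_MIN = -150.0, V_MAX = 100.0, DV_TAB = 0.05;
const int N_TAB = (int)((V_MAX - V_MIN) / DV_TAB) + 1;

// gate indices
enum { G_MNA = 0, G_HNA, G_MK, G_MSPK, G_HSPK, G_MAHP, G_MNAP, G_HNAP,
       G_MCA, G_HCA, N_GATES };

inline double clip_exp_arg(double x) {
  if (x > 500.0) return 500.0;
  if (x < -500.0) return -500.0;
  return x;
}

inline double sigmoid_inf(double v, double xh, double k) {
  return 1.0 / (1.0 + std::exp(clip_exp_arg(-(v - xh) / k)));
}

inline double cosh_tau(double v, double tmax, double th, double kt) {
  return tmax / std::cosh(clip_exp_arg((v - th) / kt));
}

// delayed-rectifier forward rate with removable singularity at v = -B
inline double rect_alpha(double v, double A, double B, double k) {
  double u = v + B;
  if (std::fabs(u) < 1e-7) return A * k;
  return A * u / (1.0 - std::exp(clip_exp_arg(-u / k)));
}

struct GateTab {
  bool active;
  std::vector<double> inf;      // steady state
  std::vector<double> dtotau;   // dt / tau(V), temperature-unscaled
  GateTab() : active(false) {}
};

// piecewise-linear schedule with constant extrapolation
struct Sched {
  std::vector<double> t, v;
  bool active;
  Sched() : active(false) {}
  double at(double tt) const {
    if (!active || t.empty()) return NA_REAL;
    size_t n = t.size();
    if (tt <= t[0]) return v[0];
    if (tt >= t[n - 1]) return v[n - 1];
    size_t j = 1;
    while (j < n && t[j] < tt) ++j;
    double f = (tt - t[j - 1]) / (t[j] - t[j - 1]);
    return v[j - 1] + f * (v[j] - v[j - 1]);
  }
};

Sched get_sched(const List& schedule, const char* name) {
  Sched s;
  if (schedule.containsElementNamed(name)) {
    List e = schedule[name];
    s.t = as<std::vector<double> >(e["time"]);
    s.v = as<std::vector<double> >(e["value"]);
    s.active = !s.t.empty();
  }
  return s;
}

void build_gate_tab(GateTab& g, const List& kin, double dt) {
  if (kin.isNULL()) return;
  List k(kin);
  std::string type = as<std::string>(k["type"]);
  NumericVector p = k["p"];
  g.active = true;
  g.inf.resize(N_TAB);
  g.dtotau.resize(N_TAB);
  for (int i = 0; i < N_TAB; ++i) {
    double v = V_MIN + i * DV_TAB;
    double inf, tau;
    if (type == "sigmoid") {
      inf = sigmoid_inf(v, p[0], p[1]);
      tau = cosh_tau(v, p[2], p[3], p[4]);
    } else if (type == "sigmoid_fixed_tau") {
      inf = sigmoid_inf(v, p[0], p[1]);
      tau = p[2];
    } else if (type == "rectifier") {
      double a = rect_alpha(v, p[0], p[1], p[2]);
      double b = p[3] * std::exp(clip_exp_arg(-(v + p[4]) / p[5]));
      inf = a / (a + b);
      tau = 1.0 / (a + b);
    } else {
      stop("unknown kinetics type '%s'", type.c_str());
    }
    if (tau < 1e-6) tau = 1e-6;
    g.inf[i] = inf;
    g.dtotau[i] = dt / tau;
  }
}

inline void tab_read(const GateTab& g, double idx, double& inf, double& dtt) {
  int i0 = (int)idx;
  double f = idx - i0;
  inf = g.inf[i0] + f * (g.inf[i0 + 1] - g.inf[i0]);
  dtt = g.dtotau[i0] + f * (g.dtotau[i0 + 1] - g.dtotau[i0]);
}

inline double vindex(double v) {
  double idx = (v - V_MIN) / DV_TAB;
  if (idx < 0.0) idx = 0.0;
  if (idx > N_TAB - 2) idx = N_TAB - 2;
  return idx;
}

} // namespace

// [[Rcpp::export]]
List sim_engine_cpp(NumericMatrix cond, List kinetics, List env, List syn,
                    List cfg, List schedule, List clamps) {
  const int N = cond.nrow();
  const double dt = as<double>(cfg["dt"]);
  const double duration = as<double>(cfg["duration"]);
  const double thresh = as<double>(cfg["spike_threshold"]);
  const double refractory = as<double>(cfg["refractory"]);
  const double record_dt = as<double>(cfg["record_dt"]);
  IntegerVector record_idx = cfg["record_idx"]; // 1-based neuron ids, may be empty
  const double init_v = as<double>(cfg["init_v"]);

  const long n_steps = (long)std::floor(duration / dt + 0.5);

  // conductance columns
  std::vector<double> g_na(N), g_k(N), g_spk(N), g_ahp(N), g_nap(N),
      g_ca(N), g_leak0(N), g_tonic(N);
  for (int i = 0; i < N; ++i) {
    g_na[i] = cond(i, 0); g_k[i] = cond(i, 1); g_spk[i] = cond(i, 2);
    g_ahp[i] = cond(i, 3); g_nap[i] = cond(i, 4); g_ca[i] = cond(i, 5);
    g_leak0[i] = cond(i, 6); g_tonic[i] = cond(i, 7);
  }
  bool any_spk = false, any_ahp = false, any_ca = false;
  for (int i = 0; i < N; ++i) {
    if (g_spk[i] > 0) any_spk = true;
    if (g_ahp[i] > 0) any_ahp = true;
    if (g_ca[i] > 0) any_ca = true;
  }

  // environment baseline
  double cap0 = as<double>(env["cap"]);
  double e_syn = as<double>(env["e_syn"]);
  double e_ca = as<double>(env["e_ca"]);
  double na_in0 = as<double>(env["na_in"]);
  double na_out = as<double>(env["na_out"]);
  double k_in = as<double>(env["k_in"]);
  double k_bath0 = as<double>(env["k_bath"]);
  double p_na = as<double>(env["p_na"]);
  double p_k = as<double>(env["p_k"]);
  double temp0 = as<double>(env["temperature"]);
  double t_ref = as<double>(env["t_ref"]);
  double q10 = as<double>(env["q10"]);
  double dv_half0 = as<double>(env["dv_half_na"]);

  // kinetics tables
  GateTab tabs[N_GATES];
  CharacterVector gate_names = kinetics.names();
  const char* expect[N_GATES] = {"m_na", "h_na", "m_k", "m_spk", "h_spk",
                                 "m_ahp", "m_nap", "h_nap", "m_ca", "h_ca"};
  for (int g = 0; g < N_GATES; ++g) {
    if (kinetics.containsElementNamed(expect[g])) {
      RObject k = kinetics[expect[g]];
      if (!k.isNULL()) build_gate_tab(tabs[g], List(k), dt);
    }
  }
  if (!any_spk) { tabs[G_MSPK].active = false; tabs[G_HSPK].active = false; }
  if (!any_ahp) { tabs[G_MAHP].active = false; }
  if (!any_ca) { tabs[G_MCA].active = false; tabs[G_HCA].active = false; }
  if (any_ca && (!tabs[G_MCA].active || !tabs[G_HCA].active))
    stop("g_ca > 0 but calcium kinetics not supplied");

  // fuse active-gate tables into one row-major array so each step touches
  // a handful of contiguous cache lines instead of one pair per gate
  std::vector<int> act;            // active gate ids, in enum order
  std::vector<int> act_shifted;    // 1 if the gate midpoint shifts
  for (int g = 0; g < N_GATES; ++g)
    if (tabs[g].active) {
      act.push_back(g);
      act_shifted.push_back(g == G_MNA || g == G_HNA || g == G_MSPK ||
                            g == G_HSPK);
    }
  const int n_act = (int)act.size();
  std::vector<double> fused((size_t)N_TAB * n_act * 2);
  for (int i = 0; i < N_TAB; ++i)
    for (int k = 0; k < n_act; ++k) {
      fused[((size_t)i * n_act + k) * 2] = tabs[act[k]].inf[i];
      fused[((size_t)i * n_act + k) * 2 + 1] = tabs[act[k]].dtotau[i];
    }

  // synapse setup
  bool coupled = false;
  std::vector<double> WT; // WT[i + j*N] = weight j -> i
  double tau_syn = as<double>(syn["tau_syn"]);
  double d0 = as<double>(syn["d0"]);
  double tau_d = as<double>(syn["tau_d"]);
  double alpha_d = as<double>(syn["alpha_d"]);
  if (!Rf_isNull(syn["w"])) {
    NumericMatrix W = syn["w"];
    if (W.nrow() != N || W.ncol() != N) stop("weight matrix must be N x N");
    WT.assign((size_t)N * N, 0.0);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        WT[(size_t)i + (size_t)j * N] = W(j, i);
    for (size_t q = 0; q < WT.size(); ++q)
      if (WT[q] != 0.0) { coupled = true; break; }
  }

  // schedules
  Sched s_dv = get_sched(schedule, "dv_half");
  Sched s_nain = get_sched(schedule, "na_in");
  Sched s_temp = get_sched(schedule, "temperature");
  Sched s_kbath = get_sched(schedule, "k_bath");
  Sched s_gton = get_sched(schedule, "g_tonic_add");
  Sched s_naps = get_sched(schedule, "g_nap_scale");
  Sched s_wsc = get_sched(schedule, "w_scale");

  // clamp events
  int n_clamp = clamps.size();
  std::vector<int> cl_trigger(n_clamp), cl_action(n_clamp);
  std::vector<double> cl_at(n_clamp);
  std::vector<bool> cl_done(n_clamp, false);
  bool want_burst_trigger = false;
  for (int c = 0; c < n_clamp; ++c) {
    List e = clamps[c];
    std::string trig = as<std::string>(e["trigger"]);
    cl_trigger[c] = (trig == "burst_init") ? 1 : 0;
    cl_at[c] = (cl_trigger[c] == 0) ? as<double>(e["at"]) : NA_REAL;
    std::string act = as<std::string>(e["action"]);
    if (act == "syn_off") cl_action[c] = 1;
    else if (act == "freeze_mnap_nonspiked") cl_action[c] = 2;
    else if (act == "freeze_hnap") cl_action[c] = 3;
    else if (act == "freeze_d") cl_action[c] = 4;
    else if (act == "freeze_hnap_d") cl_action[c] = 5;
    else stop("unknown clamp action '%s'", act.c_str());
    if (cl_trigger[c] == 1) want_burst_trigger = true;
  }

  // state
  std::vector<double> V(N, init_v), D(N, d0), drive(N, 0.0), last_spk(N, -1e18);
  std::vector<double> X[N_GATES];
  {
    double shift0 = dv_half0 + (s_dv.active ? s_dv.at(0.0) : 0.0);
    for (int g = 0; g < N_GATES; ++g) {
      if (!tabs[g].active) continue;
      X[g].assign(N, 0.0);
      bool shifted = (g == G_MNA || g == G_HNA || g == G_MSPK || g == G_HSPK);
      double idx = vindex(init_v - (shifted ? shift0 : 0.0));
      double inf, dtt;
      tab_read(tabs[g], idx, inf, dtt);
      for (int i = 0; i < N; ++i) X[g][i] = inf;
    }
  }
  std::vector<bool> frz_mnap(N, false), frz_hnap(N, false), frz_d(N, false);
  bool syn_enabled = true;

  // spike log
  std::vector<double> spk_t;
  std::vector<int> spk_id;
  spk_t.reserve(4096); spk_id.reserve(4096);

  // recording
  long rec_every = (record_dt > 0) ? std::max(1L, (long)std::floor(record_dt / dt + 0.5)) : 0;
  int n_rec_neuron = record_idx.size();
  long n_rec = (rec_every > 0) ? (n_steps / rec_every + 1) : 0;
  std::vector<double> rec_time, rec_hnap, rec_mnap, rec_d, rec_drive;
  std::vector<double> rec_v; // n_rec x n_rec_neuron column-major
  if (rec_every > 0) {
    rec_time.reserve(n_rec); rec_hnap.reserve(n_rec); rec_mnap.reserve(n_rec);
    rec_d.reserve(n_rec); rec_drive.reserve(n_rec);
    rec_v.reserve((size_t)n_rec * n_rec_neuron);
  }

  // online burst-initiation detector (smoothed network-mean h_NaP)
  const double smooth_ms = 50.0;
  const int smooth_n = std::max(1, (int)std::floor(smooth_ms / dt + 0.5));
  std::vector<double> ring(smooth_n, 0.0);
  int ring_pos = 0; long ring_fill = 0; double ring_sum = 0.0;
  // population-burst arming: 20 ms spike-count bins
  const double arm_bin = 20.0;
  long arm_bin_steps = std::max(1L, (long)std::floor(arm_bin / dt + 0.5));
  long bin_count = 0; long bin_step = 0;
  double burst_rate_thr = std::max(3.0, 0.05 * N); // spikes per 20 ms network-wide
  bool burst_active = false;
  double last_burst_end = NA_REAL, quiet_since = 0.0;
  int bursts_completed = 0;
  bool detector_armed = false, detector_fired = false;
  double hbar_runmax = -1.0;
  double trigger_time = NA_REAL;

  std::vector<double> ev_time; std::vector<int> ev_action;

  std::vector<int> spikers; spikers.reserve(64);

  for (long step = 0; step <= n_steps; ++step) {
    double t = step * dt;

    // --- per-step environment scalars -----------------------------------
    double na_in = s_nain.active ? s_nain.at(t) : na_in0;
    double k_bath = s_kbath.active ? s_kbath.at(t) : k_bath0;
    double temp = s_temp.active ? s_temp.at(t) : temp0;
    double shift = dv_half0 + (s_dv.active ? s_dv.at(t) : 0.0);
    double gton_add = s_gton.active ? s_gton.at(t) : 0.0;
    double nap_scale = s_naps.active ? s_naps.at(t) : 1.0;
    double w_scale = s_wsc.active ? s_wsc.at(t) : 1.0;

    double e_na = 26.54 * std::log(na_out / na_in);
    double e_k = 26.54 * std::log(k_bath / k_in);
    double e_leak = -26.54 * std::log((p_na * na_in + p_k * k_in) /
                                      (p_na * na_out + p_k * k_bath));
    double rate_mult = std::pow(q10, (temp - t_ref) / 10.0);
    double cap = cap0 * std::pow(1.003, temp - t_ref);
    // K_bath rescales the leak conductance through its distribution mean
    double leak_fac = std::exp((k_bath - 3.425) / 4.05) /
                      std::exp((k_bath0 - 3.425) / 4.05);
    double syn_decay = std::exp(-dt * rate_mult / tau_syn);
    double d_rec = dt * rate_mult / tau_d;

    // --- record (state at time t, before the step) -----------------------
    if (rec_every > 0 && step % rec_every == 0) {
      rec_time.push_back(t);
      double sh = 0, sm = 0, sd = 0, sg = 0;
      for (int i = 0; i < N; ++i) {
        if (tabs[G_HNAP].active) sh += X[G_HNAP][i];
        if (tabs[G_MNAP].active) sm += X[G_MNAP][i];
        sd += D[i];
        sg += drive[i];
      }
      rec_hnap.push_back(tabs[G_HNAP].active ? sh / N : NA_REAL);
      rec_mnap.push_back(tabs[G_MNAP].active ? sm / N : NA_REAL);
      rec_d.push_back(sd / N);
      rec_drive.push_back(sg / N);
      for (int r = 0; r < n_rec_neuron; ++r)
        rec_v.push_back(V[record_idx[r] - 1]);
    }
    if (step == n_steps) break;

    // --- time-triggered clamps -------------------------------------------
    for (int c = 0; c < n_clamp; ++c) {
      if (cl_done[c] || cl_trigger[c] != 0 || t < cl_at[c]) continue;
      cl_done[c] = true;
      ev_time.push_back(t); ev_action.push_back(cl_action[c]);
      switch (cl_action[c]) {
        case 1: syn_enabled = false; break;
        case 2: {
          double lookback = ISNAN(last_burst_end) ? 1000.0 : (t - last_burst_end);
          for (int i = 0; i < N; ++i)
            if (t - last_spk[i] > lookback) frz_mnap[i] = true;
          break;
        }
        case 3: for (int i = 0; i < N; ++i) frz_hnap[i] = true; break;
        case 4: for (int i = 0; i < N; ++i) frz_d[i] = true; break;
        case 5: for (int i = 0; i < N; ++i) { frz_hnap[i] = true; frz_d[i] = true; } break;
      }
    }

    // --- neuron update ----------------------------------------------------
    spikers.clear();
    double hbar_sum = 0.0;
    for (int i = 0; i < N; ++i) {
      double v = V[i];
      double idx = vindex(v);
      double idx_s = vindex(v - shift);

      double i_total = 0.0;

      // I_Na
      double mna = X[G_MNA][i], hna = X[G_HNA][i];
      i_total += g_na[i] * mna * mna * mna * hna * (v - e_na);
      // I_K
      double mk = X[G_MK][i];
      double mk2 = mk * mk;
      i_total += g_k[i] * mk2 * mk2 * (v - e_k);
      // I_SPK
      if (tabs[G_MSPK].active)
        i_total += g_spk[i] * X[G_MSPK][i] * X[G_HSPK][i] * (v - e_na);
      // I_AHP
      if (tabs[G_MAHP].active)
        i_total += g_ahp[i] * X[G_MAHP][i] * (v - e_k);
      // I_NaP
      double hnap = tabs[G_HNAP].active ? X[G_HNAP][i] : 1.0;
      i_total += g_nap[i] * nap_scale * X[G_MNAP][i] * hnap * (v - e_na);
      // I_Ca
      if (tabs[G_MCA].active)
        i_total += g_ca[i] * X[G_MCA][i] * X[G_HCA][i] * (v - e_ca);
      // leak, tonic, synaptic
      i_total += g_leak0[i] * leak_fac * (v - e_leak);
      i_total += (g_tonic[i] + gton_add) * (v - e_syn);
      i_total += drive[i] * (v - e_syn);

      double v_new = v + dt * (-i_total) / cap;

      // gate updates (old V), reading the fused interpolation rows
      {
        int i0u = (int)idx; double fu = idx - i0u;
        int i0s = (int)idx_s; double fs = idx_s - i0s;
        const double* r0u = &fused[(size_t)i0u * n_act * 2];
        const double* r1u = r0u + (size_t)n_act * 2;
        const double* r0s = &fused[(size_t)i0s * n_act * 2];
        const double* r1s = r0s + (size_t)n_act * 2;
        for (int k = 0; k < n_act; ++k) {
          int g = act[k];
          if (g == G_MNAP && frz_mnap[i]) continue;
          if (g == G_HNAP && frz_hnap[i]) continue;
          const double* a; const double* b; double f;
          if (act_shifted[k]) { a = r0s; b = r1s; f = fs; }
          else { a = r0u; b = r1u; f = fu; }
          double inf = a[2 * k] + f * (b[2 * k] - a[2 * k]);
          double dtt = a[2 * k + 1] + f * (b[2 * k + 1] - a[2 * k + 1]);
          double x = X[g][i] + rate_mult * dtt * (inf - X[g][i]);
          if (x < 0.0) x = 0.0; else if (x > 1.0) x = 1.0;
          X[g][i] = x;
        }
      }

      // depression recovery
      if (!frz_d[i]) {
        D[i] += d_rec * (d0 - D[i]);
        if (D[i] > d0) D[i] = d0;
      }

      if (!std::isfinite(v_new))
        stop("non-finite membrane potential at t = %.3f ms, neuron %d", t, i + 1);
      // spike: upward crossing of threshold with refractory lockout
      if (v < thresh && v_new >= thresh && (t - last_spk[i]) >= refractory) {
        spk_t.push_back(t + dt);
        spk_id.push_back(i + 1);
        last_spk[i] = t + dt;
        spikers.push_back(i);
      }
      V[i] = v_new;
      if (tabs[G_HNAP].active) hbar_sum += X[G_HNAP][i];
    }

    // --- synaptic transmission -------------------------------------------
    if (coupled) {
      for (int i = 0; i < N; ++i) drive[i] *= syn_decay;
      if (syn_enabled && w_scale > 0.0) {
        for (size_t s = 0; s < spikers.size(); ++s) {
          int j = spikers[s];
          double wd = w_scale * D[j]; // D at spike time, before depression
          const double* col = &WT[(size_t)j * N];
          for (int i = 0; i < N; ++i) drive[i] += wd * col[i];
        }
      }
    }
    // per-spike synaptic depression (applies whether or not transmission on)
    for (size_t s = 0; s < spikers.size(); ++s) {
      int j = spikers[s];
      if (!frz_d[j]) D[j] *= (1.0 - alpha_d);
    }

    // --- burst-initiation detector ---------------------------------------
    if (want_burst_trigger && tabs[G_HNAP].active && !detector_fired) {
      double hbar = hbar_sum / N;
      ring_sum += hbar - ring[ring_pos];
      ring[ring_pos] = hbar;
      ring_pos = (ring_pos + 1) % smooth_n;
      if (ring_fill < smooth_n) ++ring_fill;
      double hsm = ring_sum / ring_fill;

      bin_count += (long)spikers.size();
      if (++bin_step >= arm_bin_steps) {
        bool high = bin_count >= burst_rate_thr;
        if (high && !burst_active) burst_active = true;
        if (!high && burst_active) {
          quiet_since += arm_bin;
          if (quiet_since >= 100.0) {
            burst_active = false;
            last_burst_end = t;
            ++bursts_completed;
            quiet_since = 0.0;
            hbar_runmax = -1.0;
          }
        } else if (high) {
          quiet_since = 0.0;
        }
        bin_count = 0; bin_step = 0;
      }
      if (bursts_completed >= 1 && !burst_active) detector_armed = true;
      if (detector_armed) {
        if (hsm > hbar_runmax) hbar_runmax = hsm;
        else if (hbar_runmax > 0 && hsm < hbar_runmax - 1e-5) {
          detector_fired = true;
          trigger_time = t;
          for (int c = 0; c < n_clamp; ++c) {
            if (cl_done[c] || cl_trigger[c] != 1) continue;
            cl_done[c] = true;
            ev_time.push_back(t); ev_action.push_back(cl_action[c]);
            switch (cl_action[c]) {
              case 1: syn_enabled = false; break;
              case 2: {
                double lookback = ISNAN(last_burst_end) ? 1000.0 : (t - last_burst_end);
                if (lookback < 1.0) lookback = 1000.0;
                for (int i = 0; i < N; ++i)
                  if (t - last_spk[i] > lookback) frz_mnap[i] = true;
                break;
              }
              case 3: for (int i = 0; i < N; ++i) frz_hnap[i] = true; break;
              case 4: for (int i = 0; i < N; ++i) frz_d[i] = true; break;
              case 5: for (int i = 0; i < N; ++i) { frz_hnap[i] = true; frz_d[i] = true; } break;
            }
          }
        }
      }
    }
  }

  // final state snapshot
  List gates_out;
  for (int g = 0; g < N_GATES; ++g)
    if (tabs[g].active) gates_out[expect[g]] = NumericVector(X[g].begin(), X[g].end());

  List out = List::create(
      _["spike_time"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["spike_neuron"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["trigger_time"] = trigger_time,
      _["event_time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["event_action"] = IntegerVector(ev_action.begin(), ev_action.end()),
      _["final_v"] = NumericVector(V.begin(), V.end()),
      _["final_d"] = NumericVector(D.begin(), D.end()),
      _["final_gates"] = gates_out);
  if (rec_every > 0) {
    long nr = rec_time.size();
    NumericMatrix vm(nr, n_rec_neuron);
    for (long r = 0; r < nr; ++r)
      for (int c2 = 0; c2 < n_rec_neuron; ++c2)
        vm(r, c2) = rec_v[(size_t)r * n_rec_neuron + c2];
    out["trace_time"] = NumericVector(rec_time.begin(), rec_time.end());
    out["trace_v"] = vm;
    out["trace_mean_hnap"] = NumericVector(rec_hnap.begin(), rec_hnap.end());
    out["trace_mean_mnap"] = NumericVector(rec_mnap.begin(), rec_mnap.end());
    out["trace_mean_d"] = NumericVector(rec_d.begin(), rec_d.end());
    out["trace_mean_drive"] = NumericVector(rec_drive.begin(), rec_drive.end());
  }
  return out;
}
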
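// Time-stepped co-evolution of the three-population LIF network.
//
// Units: time ms, voltage mV, capacitance nF, conductance uS, current nA
// (uS * mV == nA, nA / nF == mV/ms, so the Euler update needs no unit
// conversion factors).
//
// Population order everywhere: EX, then INf, then INs (global neuron index).
// Per-source-neuron gating: each EX neuron owns one AMPA and one NMDA gating
// pair (x, s), each INf neuron one fast-GABA gating, each INs neuron one
// slow-GABA gating; a target sums the gatings of its afferents and scales by
// the projection conductance.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// ds/dt = gain*x*(1 - s) - s/tau_d, advanced one step with gain*x frozen
// (exponential Euler on the linearised ODE).  Keeps s in [0, 1) for any
// non-negative x, which is the saturation contract.
inline double step_two_stage_s(double s, double a, double inv_tau_d, double dt) {
  const double denom = a + inv_tau_d;
  if (denom <= 0.0) return s;
  const double decay = std::exp(-denom * dt);
  return s * decay + (a / denom) * (1.0 - decay);
}

inline double mg_block(double v, double mg, double slope, double scale) {
  return 1.0 / (1.0 + mg * std::exp(-slope * v) / scale);
}

// adjacency list: for every source neuron, the global indices of its targets
typedef std::vector< std::vector<int> > AdjList;

AdjList build_adj(const IntegerMatrix& m, int offset_target) {
  AdjList out(m.nrow());
  for (int j = 0; j < m.nrow(); ++j)
    for (int i = 0; i < m.ncol(); ++i)
      if (m(j, i) != 0) out[j].push_back(i + offset_target);
  return out;
}

void append_adj(AdjList& dest, const AdjList& src) {
  for (size_t j = 0; j < src.size(); ++j)
    dest[j].insert(dest[j].end(), src[j].begin(), src[j].end());
}

} // namespace

// [[Rcpp::export]]
List simulate_network_cpp(int n_ex, int n_inf, int n_ins,
                          NumericVector memb_C, NumericVector memb_gL,
                          NumericVector memb_Vrest, NumericVector memb_Vth,
                          NumericVector memb_Vreset, NumericVector memb_tref,
                          List kin, NumericVector w, bool all_to_all, List adj,
                          List in_scale, NumericVector i_background,
                          double stim_amp,
                          double stim_onset, double stim_dur,
                          NumericVector v_init, double dt, int n_steps,
                          int record_every, NumericVector delay_ms) {
  const int N = n_ex + n_inf + n_ins;
  if (i_background.size() != N) stop("background current length mismatch");
  if (v_init.size() != N) stop("v_init length mismatch");

  // kinetics
  const double tau_am_r = kin["ampa_rise"],  tau_am_d = kin["ampa_decay"];
  const double tau_nm_r = kin["nmda_rise"],  tau_nm_d = kin["nmda_decay"];
  const double gain_am  = kin["ampa_gain"],  gain_nm  = kin["nmda_gain"];
  const double tau_gf   = kin["gabaf_decay"], tau_gs  = kin["gabas_decay"];
  const double jump_gf = kin["gabaf_jump"], jump_gs = kin["gabas_jump"];
  const double e_exc = kin["e_exc"], e_gaba = kin["e_gaba"];
  const double mg = kin["mg_conc"], mg_slope = kin["mg_slope"],
               mg_scale = kin["mg_scale"];

  // per-synapse projection weights (uS), order fixed by the R wrapper
  const double w_am_ee = w[0], w_am_ef = w[1], w_am_es = w[2];
  const double w_nm_ee = w[3], w_nm_ef = w[4], w_nm_es = w[5];
  const double w_ga_ff = w[6], w_ga_fe = w[7], w_ga_fs = w[8];
  const double w_ga_ss = w[9], w_ga_se = w[10], w_ga_sf = w[11];

  const double dec_x_am = std::exp(-dt / tau_am_r);
  const double dec_x_nm = std::exp(-dt / tau_nm_r);
  const double inv_am_d = 1.0 / tau_am_d, inv_nm_d = 1.0 / tau_nm_d;
  const double dec_gf = std::exp(-dt / tau_gf);
  const double dec_gs = std::exp(-dt / tau_gs);

  // sparse adjacency (targets per source, global indices) and per-target
  // in-degree normalisation factors (keep each target's projection total
  // at the configured value despite Bernoulli in-degree fluctuations)
  AdjList adj_e, adj_f, adj_s;
  std::vector<double> sc_e, sc_f, sc_s;
  if (!all_to_all) {
    sc_e = as< std::vector<double> >(in_scale["e"]);
    sc_f = as< std::vector<double> >(in_scale["f"]);
    sc_s = as< std::vector<double> >(in_scale["s"]);
    if ((int)sc_e.size() != N || (int)sc_f.size() != N || (int)sc_s.size() != N)
      stop("in_scale length mismatch");
    adj_e = build_adj(as<IntegerMatrix>(adj["ee"]), 0);
    append_adj(adj_e, build_adj(as<IntegerMatrix>(adj["ef"]), n_ex));
    append_adj(adj_e, build_adj(as<IntegerMatrix>(adj["es"]), n_ex + n_inf));
    adj_f = build_adj(as<IntegerMatrix>(adj["fe"]), 0);
    append_adj(adj_f, build_adj(as<IntegerMatrix>(adj["ff"]), n_ex));
    append_adj(adj_f, build_adj(as<IntegerMatrix>(adj["fs"]), n_ex + n_inf));
    adj_s = build_adj(as<IntegerMatrix>(adj["se"]), 0);
    append_adj(adj_s, build_adj(as<IntegerMatrix>(adj["sf"]), n_ex));
    append_adj(adj_s, build_adj(as<IntegerMatrix>(adj["ss"]), n_ex + n_inf));
  }

  // state
  std::vector<double> V(v_init.begin(), v_init.end());
  std::vector<double> refr(N, 0.0);
  std::vector<double> x_am(n_ex, 0.0), s_am(n_ex, 0.0);
  std::vector<double> x_nm(n_ex, 0.0), s_nm(n_ex, 0.0);
  std::vector<double> s_gf(n_inf, 0.0), s_gs(n_ins, 0.0);

  std::vector<double> am_in(N), nm_in(N), gf_in(N), gs_in(N);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  // synaptic transmission delays, one per receptor class (ampa, nmda,
  // gaba_fast, gaba_slow): presynaptic gating jumps are applied
  // `d_*` steps after threshold crossing (ring buffers of spike flags;
  // EX spikes are delivered twice, once per glutamate class)
  if (delay_ms.size() != 4) stop("delay_ms must have 4 entries");
  const int d_am = std::max(0, (int)std::lround(delay_ms[0] / dt));
  const int d_nm = std::max(0, (int)std::lround(delay_ms[1] / dt));
  const int d_gf = std::max(0, (int)std::lround(delay_ms[2] / dt));
  const int d_gs = std::max(0, (int)std::lround(delay_ms[3] / dt));
  const int ring = std::max(std::max(d_am, d_nm), std::max(d_gf, d_gs)) + 1;
  std::vector<char> ring_am((size_t)ring * n_ex, 0);
  std::vector<char> ring_nm((size_t)ring * n_ex, 0);
  std::vector<char> ring_gf((size_t)ring * n_inf, 0);
  std::vector<char> ring_gs((size_t)ring * n_ins, 0);

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix v_ex_rec(n_rec, n_ex);
  NumericVector t_rec(n_rec);
  for (int i = 0; i < n_ex; ++i) v_ex_rec(0, i) = V[i];
  t_rec[0] = 0.0;
  int rec_row = 1;

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;

    // 0. deliver gating jumps for spikes whose delay has elapsed
    {
      const size_t slot = (size_t)(step % ring);
      char* am = &ring_am[slot * n_ex];
      char* nm = &ring_nm[slot * n_ex];
      for (int j = 0; j < n_ex; ++j) {
        if (am[j]) { x_am[j] += 1.0; am[j] = 0; }
        if (nm[j]) { x_nm[j] += 1.0; nm[j] = 0; }
      }
      char* gf = &ring_gf[slot * n_inf];
      for (int j = 0; j < n_inf; ++j)
        if (gf[j]) { s_gf[j] += jump_gf * (1.0 - s_gf[j]); gf[j] = 0; }
      char* gs = &ring_gs[slot * n_ins];
      for (int j = 0; j < n_ins; ++j)
        if (gs[j]) { s_gs[j] += jump_gs * (1.0 - s_gs[j]); gs[j] = 0; }
    }

    // 1. synaptic gating relaxation (decay + two-stage drive)
    for (int j = 0; j < n_ex; ++j) {
      s_am[j] = step_two_stage_s(s_am[j], gain_am * x_am[j], inv_am_d, dt);
      s_nm[j] = step_two_stage_s(s_nm[j], gain_nm * x_nm[j], inv_nm_d, dt);
      x_am[j] *= dec_x_am;
      x_nm[j] *= dec_x_nm;
    }
    for (int j = 0; j < n_inf; ++j) s_gf[j] *= dec_gf;
    for (int j = 0; j < n_ins; ++j) s_gs[j] *= dec_gs;

    // 2. afferent gating sums per target
    if (all_to_all) {
      double S_am = 0.0, S_nm = 0.0, S_gf = 0.0, S_gs = 0.0;
      for (int j = 0; j < n_ex; ++j) { S_am += s_am[j]; S_nm += s_nm[j]; }
      for (int j = 0; j < n_inf; ++j) S_gf += s_gf[j];
      for (int j = 0; j < n_ins; ++j) S_gs += s_gs[j];
      for (int i = 0; i < N; ++i) {
        am_in[i] = S_am; nm_in[i] = S_nm; gf_in[i] = S_gf; gs_in[i] = S_gs;
      }
      // no autapses: remove own gating from the recurrent sum
      for (int i = 0; i < n_ex; ++i) { am_in[i] -= s_am[i]; nm_in[i] -= s_nm[i]; }
      for (int i = 0; i < n_inf; ++i) gf_in[n_ex + i] -= s_gf[i];
      for (int i = 0; i < n_ins; ++i) gs_in[n_ex + n_inf + i] -= s_gs[i];
    } else {
      std::fill(am_in.begin(), am_in.end(), 0.0);
      std::fill(nm_in.begin(), nm_in.end(), 0.0);
      std::fill(gf_in.begin(), gf_in.end(), 0.0);
      std::fill(gs_in.begin(), gs_in.end(), 0.0);
      for (int j = 0; j < n_ex; ++j) {
        const double sa = s_am[j], sn = s_nm[j];
        const std::vector<int>& tg = adj_e[j];
        for (size_t k = 0; k < tg.size(); ++k) {
          am_in[tg[k]] += sa; nm_in[tg[k]] += sn;
        }
      }
      for (int j = 0; j < n_inf; ++j) {
        const double sf = s_gf[j];
        const std::vector<int>& tg = adj_f[j];
        for (size_t k = 0; k < tg.size(); ++k) gf_in[tg[k]] += sf;
      }
      for (int j = 0; j < n_ins; ++j) {
        const double ss = s_gs[j];
        const std::vector<int>& tg = adj_s[j];
        for (size_t k = 0; k < tg.size(); ++k) gs_in[tg[k]] += ss;
      }
      for (int i = 0; i < N; ++i) {
        am_in[i] *= sc_e[i]; nm_in[i] *= sc_e[i];
        gf_in[i] *= sc_f[i]; gs_in[i] *= sc_s[i];
      }
    }

    const bool stim_on = (t_now >= stim_onset) && (t_now < stim_onset + stim_dur);

    // 3. membrane update + threshold/reset + output gating jumps
    for (int i = 0; i < N; ++i) {
      const int p = (i < n_ex) ? 0 : (i < n_ex + n_inf ? 1 : 2);
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        V[i] = memb_Vreset[p];
        continue;
      }
      const double v = V[i];
      double w_am, w_nm, w_gf, w_gs;
      if (p == 0)      { w_am = w_am_ee; w_nm = w_nm_ee; w_gf = w_ga_fe; w_gs = w_ga_se; }
      else if (p == 1) { w_am = w_am_ef; w_nm = w_nm_ef; w_gf = w_ga_ff; w_gs = w_ga_sf; }
      else             { w_am = w_am_es; w_nm = w_nm_es; w_gf = w_ga_fs; w_gs = w_ga_ss; }

      double i_syn = -w_am * am_in[i] * (v - e_exc)
                     - w_nm * nm_in[i] * mg_block(v, mg, mg_slope, mg_scale) * (v - e_exc)
                     - w_gf * gf_in[i] * (v - e_gaba)
                     - w_gs * gs_in[i] * (v - e_gaba);
      double i_ext = i_background[i];
      if (stim_on && p == 0) i_ext += stim_amp;

      double v_new = v + dt / memb_C[p] *
                     (-memb_gL[p] * (v - memb_Vrest[p]) + i_syn + i_ext);
      if (!std::isfinite(v_new))
        stop("membrane potential diverged at step %d (t = %.2f ms), neuron %d",
             step, t_now, i + 1);

      if (v_new >= memb_Vth[p]) {
        sp_id.push_back(i + 1);                 // 1-based for R
        sp_t.push_back(t_now + dt);
        v_new = memb_Vreset[p];
        refr[i] = memb_tref[p];
        if (p == 0) {
          ring_am[(size_t)((step + d_am) % ring) * n_ex + i] = 1;
          ring_nm[(size_t)((step + d_nm) % ring) * n_ex + i] = 1;
        } else if (p == 1) {
          ring_gf[(size_t)((step + d_gf) % ring) * n_inf + (i - n_ex)] = 1;
        } else {
          ring_gs[(size_t)((step + d_gs) % ring) * n_ins + (i - n_ex - n_inf)] = 1;
        }
      }
      V[i] = v_new;
    }

    if ((step + 1) % record_every == 0 && rec_row < n_rec) {
      for (int i = 0; i < n_ex; ++i) v_ex_rec(rec_row, i) = V[i];
      t_rec[rec_row] = (step + 1) * dt;
      ++rec_row;
    }
  }

  return List::create(_["spike_id"] = wrap(sp_id),
                      _["spike_time"] = wrap(sp_t),
                      _["time"] = t_rec,
                      _["v_ex"] = v_ex_rec);
}

// Single downstream LIF readout driven by the pooled EX spike train through
// one shared two-stage AMPA gating (x jumps by 1 at every afferent spike).
// [[Rcpp::export]]
List simulate_downstream_cpp(NumericVector ex_spike_times, double weight,
                             double tau_rise, double tau_decay, double gain,
                             double e_exc, double C, double gL, double Vrest,
                             double Vth, double Vreset, double tref,
                             double i_bg, double dt, int n_steps) {
  std::vector<double> sp;
  double V = Vrest, refr = 0.0, x = 0.0, s = 0.0;
  const double dec_x = std::exp(-dt / tau_rise);
  const double inv_d = 1.0 / tau_decay;
  int k = 0;
  const int n_in = ex_spike_times.size(); // must be sorted ascending

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;
    s = step_two_stage_s(s, gain * x, inv_d, dt);
    x *= dec_x;
    while (k < n_in && ex_spike_times[k] <= t_now + dt) { x += 1.0; ++k; }

    if (refr > 0.0) { refr -= dt; V = Vreset; continue; }
    const double i_syn = -weight * s * (V - e_exc);
    double v_new = V + dt / C * (-gL * (V - Vrest) + i_syn + i_bg);
    if (!std::isfinite(v_new)) stop("downstream membrane potential diverged");
    if (v_new >= Vth) {
      sp.push_back(t_now + dt);
      v_new = Vreset;
      refr = tref;
    }
    V = v_new;
  }
  return List::create(_["spike_time"] = wrap(sp));
}
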
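// Time-stepping engine for the thalamocortical ring network.
//
// Hybrid integration: conductances decay by their exact exponential between
// spike events (jumps applied once per step, one-step synaptic latency);
// membrane equations advance by forward Euler at the configured dt with
// clamp-and-reset threshold handling at step boundaries.
//
// Populations: n_exc L5 pyramidal-tract cells (soma + apical compartment),
// n_inh basket cells, n_thal matrix-thalamus cells. All randomness goes
// through R's RNG so a run is reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double logistic_f(double v) {
  return 1.0 / (1.0 + std::exp(-(v + 38.0) / 6.0));
}

inline double nmda_gate_c(double v) {
  double x = (v + 80.0) / 60.0;
  x *= x;
  return x / (1.0 + x);
}

// Knuth Poisson sampler; p0 = exp(-lambda) precomputed.
inline int rpois_small(double p0) {
  if (p0 >= 1.0) return 0;
  int k = 0;
  double p = unif_rand();
  while (p > p0) {
    ++k;
    p *= unif_rand();
  }
  return k;
}

struct IzhiP {
  double C, k, vr, vt, a, b, vpeak;
};

IzhiP izhi_from_list(const List& p) {
  IzhiP q;
  q.C = p["C"]; q.k = p["k"]; q.vr = p["v_r"]; q.vt = p["v_t"];
  q.a = p["a"]; q.b = p["b"]; q.vpeak = p["v_peak"];
  return q;
}

} // namespace

// [[Rcpp::export]]
List simulate_tc_cpp(List cfg) {
  const int n_exc = cfg["n_exc"], n_inh = cfg["n_inh"], n_thal = cfg["n_thal"];
  const int n_steps = cfg["n_steps"], record_every = cfg["record_every"];
  const double dt = cfg["dt"];
  const int burn_steps = cfg["burn_steps"];
  const bool noise_free = cfg["noise_free"];
  const bool record_traces = cfg["record_traces"];

  // cell parameters
  List soma_l = cfg["soma"], basket_l = cfg["basket"], thal_l = cfg["thalamus"],
       ap_l = cfg["apical"];
  IzhiP ps = izhi_from_list(soma_l), pb = izhi_from_list(basket_l),
        pt = izhi_from_list(thal_l);
  const double c_rs = soma_l["c_rs"], d_rs = soma_l["d_rs"],
               c_ib = soma_l["c_ib"], d_ib = soma_l["d_ib"];
  const double cb = basket_l["c"], db = basket_l["d"];
  const double ct = thal_l["c"], dth = thal_l["d"];
  const double apC = ap_l["C"], apl = ap_l["l"], apg = ap_l["g"],
               apm = ap_l["m"], apvr = ap_l["v_r"], apa = ap_l["a"],
               apb = ap_l["b"], plateau_thr = ap_l["v_plateau_threshold"];
  const int bap_delay = ap_l["bap_delay_steps"],
            bap_dur = ap_l["bap_duration_steps"];

  // synapse constants
  List syn = cfg["synapse"];
  const double dec_ampa = std::exp(-dt / as<double>(syn["tau_ampa"]));
  const double dec_gaba = std::exp(-dt / as<double>(syn["tau_gaba"]));
  const double dec_nmda = std::exp(-dt / as<double>(syn["tau_nmda"]));
  const double dec_coup = std::exp(-dt / as<double>(syn["tau_coupling"]));
  const double dec_adapt = std::exp(-dt / as<double>(syn["tau_adapt"]));
  const double dg_adapt = syn["delta_g_adapt"];
  const double E_exc = syn["E_exc"], E_inh = syn["E_inh"],
               E_adapt = syn["E_adapt"], nmda_cap = syn["nmda_cap"];

  // weights (post x pre, column-major)
  NumericMatrix W_ee_a = cfg["W_ee_ampa"], W_ee_n = cfg["W_ee_nmda"],
                W_ei = cfg["W_ei"], W_ie = cfg["W_ie"];
  const double w_e_th = cfg["w_e_th"], w_th_d_a = cfg["w_th_d_ampa"],
               w_th_d_n = cfg["w_th_d_nmda"];
  IntegerVector thal_map = cfg["thal_map"]; // 0-based thalamic partner per E cell

  // drives: per-step Poisson means (rate * dt / 1000)
  NumericVector lam_soma = cfg["lam_soma"], lam_basket = cfg["lam_basket"],
                lam_thal = cfg["lam_thal"], lam_apical = cfg["lam_apical"],
                lam_riv_l = cfg["lam_riv_left"], lam_riv_r = cfg["lam_riv_right"];
  const double w_ext = cfg["w_ext"], w_ext_thal = cfg["w_ext_thal"],
               w_ext_basket = cfg["w_ext_basket"],
               w_ext_apical = cfg["w_ext_apical"],
               w_ext_riv = cfg["w_ext_riv"];
  const bool ext_nmda = cfg["ext_nmda"];
  const bool riv_nmda = cfg["riv_nmda"];
  const bool ee_to_apical = cfg["ee_to_apical"];
  NumericVector pulse_amp = cfg["pulse_amp_cell"];
  const int pulse_on = cfg["pulse_on_step"], pulse_off = cfg["pulse_off_step"];
  NumericVector pert_apical = cfg["pert_apical"], pert_thal = cfg["pert_thal"];
  NumericVector kick_amp = cfg["kick_amp_cell"];
  const int kick_on = cfg["kick_on_step"], kick_off = cfg["kick_off_step"];
  NumericVector init_v_offset = cfg["init_v_offset"];
  const int riv_right_on = cfg["riv_right_on_step"];

  // precompute exp(-lambda) (stochastic mode) per cell/source
  auto p0_of = [](const NumericVector& lam) {
    std::vector<double> p0(lam.size());
    for (int i = 0; i < lam.size(); ++i) p0[i] = std::exp(-lam[i]);
    return p0;
  };
  std::vector<double> p0_soma = p0_of(lam_soma), p0_basket = p0_of(lam_basket),
                      p0_thal = p0_of(lam_thal), p0_apical = p0_of(lam_apical),
                      p0_riv_l = p0_of(lam_riv_l), p0_riv_r = p0_of(lam_riv_r);

  // state
  std::vector<double> v_s(n_exc, ps.vr), u_s(n_exc, 0.0);
  std::vector<int> regime(n_exc, 0); // 0 = RS, 1 = IB
  std::vector<double> g_ampa_s(n_exc, 0.0), g_nmda_s(n_exc, 0.0),
      g_gaba_s(n_exc, 0.0), g_adapt(n_exc, 0.0);
  std::vector<double> v_d(n_exc, apvr), u_d(n_exc, 0.0),
      g_ampa_d(n_exc, 0.0), g_nmda_d(n_exc, 0.0), g_coup(n_exc, 0.0);
  std::vector<double> v_b(n_inh, pb.vr), u_b(n_inh, 0.0),
      g_ampa_b(n_inh, 0.0), g_nmda_b(n_inh, 0.0);
  std::vector<double> v_t(n_thal, pt.vr), u_t(n_thal, 0.0),
      g_ampa_t(n_thal, 0.0);
  for (int i = 0; i < n_exc; ++i) v_s[i] += init_v_offset[i];

  // bAP windows: per E cell, (onset_step, offset_step) pairs
  std::vector<std::vector<std::pair<int, int> > > bap(n_exc);

  // previous-step spike lists
  std::vector<int> sp_e_prev, sp_i_prev, sp_t_prev;

  // spike event storage
  std::vector<int> ev_e_cell, ev_i_cell, ev_t_cell;
  std::vector<double> ev_e_t, ev_i_t, ev_t_t;

  // recorded traces
  const int n_rec = record_traces ? (n_steps / record_every) : 0;
  NumericMatrix rec_apical_I(n_rec, record_traces ? n_exc : 0);
  IntegerMatrix rec_regime(n_rec, record_traces ? n_exc : 0);
  NumericMatrix rec_coupling(n_rec, record_traces ? n_exc : 0);
  NumericVector rec_time(n_rec);
  int rec_row = 0;

  // E/I balance accumulators (soma synaptic currents and conductances,
  // post burn-in)
  double sum_exc_I = 0.0, sum_inh_I = 0.0;
  double sum_exc_g = 0.0, sum_inh_g = 0.0;
  double max_nmda = 0.0, min_g = 0.0;
  long n_balance = 0;

  const double blowup = 10.0 * std::fabs(ps.vpeak);
  std::vector<int> sp_e, sp_i, sp_t;

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = step * dt;

    // ---- 1. conductance decay ----
    for (int i = 0; i < n_exc; ++i) {
      g_ampa_s[i] *= dec_ampa; g_nmda_s[i] *= dec_nmda;
      g_gaba_s[i] *= dec_gaba; g_adapt[i] *= dec_adapt;
      g_ampa_d[i] *= dec_ampa; g_nmda_d[i] *= dec_nmda;
      g_coup[i] *= dec_coup;
    }
    for (int i = 0; i < n_inh; ++i) { g_ampa_b[i] *= dec_ampa; g_nmda_b[i] *= dec_nmda; }
    for (int i = 0; i < n_thal; ++i) g_ampa_t[i] *= dec_ampa;

    // ---- 2. recurrent jumps from last step's spikes ----
    for (size_t s = 0; s < sp_e_prev.size(); ++s) {
      const int j = sp_e_prev[s];
      const double *col_a = &W_ee_a(0, j), *col_n = &W_ee_n(0, j),
                   *col_ei = &W_ei(0, j);
      if (ee_to_apical) {
        // horizontal cortico-cortical axons ramify in L1 and contact the
        // apical tuft, alongside the matrix-thalamic afferents
        for (int i = 0; i < n_exc; ++i) {
          g_ampa_d[i] += col_a[i];
          g_nmda_d[i] += col_n[i];
        }
      } else {
        for (int i = 0; i < n_exc; ++i) {
          g_ampa_s[i] += col_a[i];
          g_nmda_s[i] += col_n[i];
        }
      }
      for (int i = 0; i < n_inh; ++i) {
        g_ampa_b[i] += col_ei[i];
        g_nmda_b[i] += col_ei[i];
      }
      g_ampa_t[thal_map[j]] += w_e_th;
      g_adapt[j] += dg_adapt;
    }
    for (size_t s = 0; s < sp_i_prev.size(); ++s) {
      const int j = sp_i_prev[s];
      const double *col = &W_ie(0, j);
      for (int i = 0; i < n_exc; ++i) g_gaba_s[i] += col[i];
    }
    for (size_t s = 0; s < sp_t_prev.size(); ++s) {
      const int jt = sp_t_prev[s];
      for (int i = 0; i < n_exc; ++i) {
        if (thal_map[i] == jt) {
          g_ampa_d[i] += w_th_d_a;
          g_nmda_d[i] += w_th_d_n;
          g_coup[i] += (1.0 - g_coup[i]); // saturating jump to 1
        }
      }
    }

    // ---- external drives ----
    if (noise_free) {
      for (int i = 0; i < n_exc; ++i) {
        const double inc_bg = w_ext * lam_soma[i];
        const double inc_rv = w_ext_riv *
          (lam_riv_l[i] + (step >= riv_right_on ? lam_riv_r[i] : 0.0));
        g_ampa_s[i] += inc_bg + inc_rv;
        if (ext_nmda) g_nmda_s[i] += inc_bg;
        if (riv_nmda) g_nmda_s[i] += inc_rv;
        const double inc_d = w_ext_apical * lam_apical[i];
        g_ampa_d[i] += inc_d;
        if (ext_nmda) g_nmda_d[i] += inc_d;
      }
      for (int i = 0; i < n_inh; ++i) {
        g_ampa_b[i] += w_ext_basket * lam_basket[i];
        if (ext_nmda) g_nmda_b[i] += w_ext_basket * lam_basket[i];
      }
      for (int i = 0; i < n_thal; ++i) g_ampa_t[i] += w_ext_thal * lam_thal[i];
    } else {
      for (int i = 0; i < n_exc; ++i) {
        int c = rpois_small(p0_soma[i]);
        int cr = 0;
        if (lam_riv_l[i] > 0) cr += rpois_small(p0_riv_l[i]);
        if (lam_riv_r[i] > 0 && step >= riv_right_on)
          cr += rpois_small(p0_riv_r[i]);
        if (c || cr) {
          g_ampa_s[i] += w_ext * c + w_ext_riv * cr;
          if (ext_nmda) g_nmda_s[i] += w_ext * c;
          if (riv_nmda) g_nmda_s[i] += w_ext_riv * cr;
        }
        int ca = rpois_small(p0_apical[i]);
        if (ca) {
          g_ampa_d[i] += w_ext_apical * ca;
          if (ext_nmda) g_nmda_d[i] += w_ext_apical * ca;
        }
      }
      for (int i = 0; i < n_inh; ++i) {
        int c = rpois_small(p0_basket[i]);
        if (c) {
          g_ampa_b[i] += w_ext_basket * c;
          if (ext_nmda) g_nmda_b[i] += w_ext_basket * c;
        }
      }
      for (int i = 0; i < n_thal; ++i) {
        int c = rpois_small(p0_thal[i]);
        if (c) g_ampa_t[i] += w_ext_thal * c;
      }
    }
    for (int i = 0; i < n_exc; ++i) {
      if (g_nmda_s[i] > nmda_cap) g_nmda_s[i] = nmda_cap;
      if (g_nmda_d[i] > nmda_cap) g_nmda_d[i] = nmda_cap;
      if (g_nmda_s[i] > max_nmda) max_nmda = g_nmda_s[i];
      if (g_nmda_d[i] > max_nmda) max_nmda = g_nmda_d[i];
      double gmin = std::min(std::min(g_ampa_s[i], g_gaba_s[i]),
                             std::min(g_ampa_d[i], g_adapt[i]));
      if (gmin < min_g) min_g = gmin;
    }
    for (int i = 0; i < n_inh; ++i) {
      if (g_nmda_b[i] > nmda_cap) g_nmda_b[i] = nmda_cap;
      if (g_nmda_b[i] > max_nmda) max_nmda = g_nmda_b[i];
    }

    const bool pulse_on_now = (step >= pulse_on && step < pulse_off);
    const bool kick_on_now = (step >= kick_on && step < kick_off);
    const bool do_rec = record_traces && (step % record_every == 0);

    sp_e.clear(); sp_i.clear(); sp_t.clear();

    // ---- 3-6. per-population updates ----
    for (int i = 0; i < n_exc; ++i) {
      // bAP contribution: overlapping windows from burst spikes sum
      int n_bap = 0;
      std::vector<std::pair<int, int> >& wq = bap[i];
      if (!wq.empty()) {
        size_t keep = 0;
        for (size_t w = 0; w < wq.size(); ++w) {
          if (wq[w].second <= step) continue; // expired
          wq[keep++] = wq[w];
          if (wq[w].first <= step) ++n_bap;
        }
        wq.resize(keep);
      }

      // apical currents (everything entering the apical equation except u_d)
      const double vd = v_d[i];
      double I_ap = g_ampa_d[i] * (E_exc - vd) +
                    nmda_gate_c(vd) * g_nmda_d[i] * (E_exc - vd) +
                    apm * n_bap + pert_apical[i];

      if (do_rec) {
        rec_apical_I(rec_row, i) = I_ap;
        rec_regime(rec_row, i) = regime[i];
        rec_coupling(rec_row, i) = g_coup[i];
      }

      // apical forward Euler
      const double dvd = (-apl * (vd - apvr) + apg * logistic_f(vd) +
                          u_d[i] + I_ap) / apC;
      const double dud = apa * (apb * (vd - apvr) - u_d[i]);
      v_d[i] = vd + dt * dvd;
      u_d[i] = u_d[i] + dt * dud;

      // plateau-gated regime switch: Bernoulli draw at plateau onset only
      if (v_d[i] > plateau_thr) {
        if (vd <= plateau_thr) { // upward crossing
          if (unif_rand() < g_coup[i]) regime[i] = 1;
        }
      } else {
        regime[i] = 0;
      }

      // somatic currents
      const double vs = v_s[i];
      double exc_I = g_ampa_s[i] * (E_exc - vs) +
                     nmda_gate_c(vs) * g_nmda_s[i] * (E_exc - vs);
      double inh_I = g_gaba_s[i] * (E_inh - vs);
      double I_s = exc_I + inh_I + g_adapt[i] * (E_adapt - vs);
      if (pulse_on_now) I_s += pulse_amp[i];
      if (kick_on_now) I_s += kick_amp[i];
      if (step >= burn_steps) {
        sum_exc_I += exc_I; sum_inh_I += inh_I;
        sum_exc_g += g_ampa_s[i] + nmda_gate_c(vs) * g_nmda_s[i];
        sum_inh_g += g_gaba_s[i];
        ++n_balance;
      }

      // soma forward Euler + reset with the active regime's pair
      double vn = vs + dt * (ps.k * (vs - ps.vr) * (vs - ps.vt) - u_s[i] + I_s) / ps.C;
      u_s[i] += dt * ps.a * (ps.b * (vs - ps.vr) - u_s[i]);
      if (vn >= ps.vpeak) {
        ev_e_cell.push_back(i); ev_e_t.push_back(t_now);
        sp_e.push_back(i);
        vn = regime[i] ? c_ib : c_rs;
        u_s[i] += regime[i] ? d_ib : d_rs;
        // schedule a bAP with probability g_coupling
        if (unif_rand() < g_coup[i])
          bap[i].push_back(std::make_pair(step + bap_delay,
                                          step + bap_delay + bap_dur));
      }
      v_s[i] = vn;
    }

    for (int i = 0; i < n_inh; ++i) {
      const double vb = v_b[i];
      const double I_b = g_ampa_b[i] * (E_exc - vb) +
                         nmda_gate_c(vb) * g_nmda_b[i] * (E_exc - vb);
      double vn = vb + dt * (pb.k * (vb - pb.vr) * (vb - pb.vt) - u_b[i] + I_b) / pb.C;
      u_b[i] += dt * pb.a * (pb.b * (vb - pb.vr) - u_b[i]);
      if (vn >= pb.vpeak) {
        ev_i_cell.push_back(i); ev_i_t.push_back(t_now);
        sp_i.push_back(i);
        vn = cb; u_b[i] += db;
      }
      v_b[i] = vn;
    }

    for (int i = 0; i < n_thal; ++i) {
      const double vt = v_t[i];
      const double I_t = g_ampa_t[i] * (E_exc - vt) + pert_thal[i];
      double vn = vt + dt * (pt.k * (vt - pt.vr) * (vt - pt.vt) - u_t[i] + I_t) / pt.C;
      u_t[i] += dt * pt.a * (pt.b * (vt - pt.vr) - u_t[i]);
      if (vn >= pt.vpeak) {
        ev_t_cell.push_back(i); ev_t_t.push_back(t_now);
        sp_t.push_back(i);
        vn = ct; u_t[i] += dth;
      }
      v_t[i] = vn;
    }

    if (do_rec) { rec_time[rec_row] = t_now; ++rec_row; }

    // blow-up diagnostics
    if (step % 1000 == 0) {
      for (int i = 0; i < n_exc; ++i) {
        if (!R_finite(v_s[i]) || !R_finite(v_d[i]) ||
            std::fabs(v_s[i]) > blowup || std::fabs(v_d[i]) > blowup)
          stop("integration blow-up at step %d (L5 cell %d)", step, i + 1);
      }
    }

    sp_e_prev.swap(sp_e); sp_i_prev.swap(sp_i); sp_t_prev.swap(sp_t);
  }

  List out = List::create(
    _["exc_cell"] = wrap(ev_e_cell), _["exc_time"] = wrap(ev_e_t),
    _["inh_cell"] = wrap(ev_i_cell), _["inh_time"] = wrap(ev_i_t),
    _["thal_cell"] = wrap(ev_t_cell), _["thal_time"] = wrap(ev_t_t),
    _["mean_exc_current"] = n_balance ? sum_exc_I / n_balance : 0.0,
    _["mean_inh_current"] = n_balance ? sum_inh_I / n_balance : 0.0,
    _["mean_exc_conductance"] = n_balance ? sum_exc_g / n_balance : 0.0,
    _["mean_inh_conductance"] = n_balance ? sum_inh_g / n_balance : 0.0,
    _["max_nmda_conductance"] = max_nmda,
    _["min_conductance"] = min_g
  );
  if (record_traces) {
    out["trace_time"] = rec_time;
    out["apical_input"] = rec_apical_I;
    out["regime"] = rec_regime;
    out["coupling"] = rec_coupling;
  }
  return out;
}
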
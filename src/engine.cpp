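#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler LIF network engine.
//
// State layout: one gating variable set per neuron attached to the *source*
// side (s_ampa_ext, s_ampa_rec, x_nmda, s_nmda for pyramidal sources, s_gaba
// for interneuron sources). Because every connection between two populations
// shares one weight and connectivity is all-to-all (self excluded), the
// weighted presynaptic sums reduce to population aggregates, giving an O(N)
// step.
//
// Stimulation semantics:
//  - galvanic (mode 2): constant per-neuron current inside the stimulation
//    window, with the depolarizing-block gate (input current zeroed for a
//    step when it exceeds the cap);
//  - pulsatile (mode 1): per-neuron current during pulse phases (sign flips
//    with the phase), with amplitude-dependent pulse-pulse (t_pp) and
//    pulse-spontaneous (t_ps) refractory clocks. A pulse arriving while the
//    t_pp clock runs renews it at t_pp/2; otherwise t_pp/t_ps start when the
//    pulse footprint ends. Gated threshold crossings leave the membrane at
//    threshold without initiating an AP.

// [[Rcpp::export]]
List simulate_trial_cpp(
    int n,
    IntegerVector pop,           // 0 P1, 1 P2, 2 NS, 3 Int
    LogicalVector is_pyr,
    NumericMatrix W,             // 4x4 source x target, 0 where unconnected
    NumericVector Cm, NumericVector gL, NumericVector EL,
    NumericVector Vth, NumericVector Vr, NumericVector tau_r,
    NumericVector g_ext, NumericVector g_arec,
    NumericVector g_nmda, NumericVector g_gaba,
    double E_ampa, double E_nmda, double E_gaba,
    double tau_ampa, double tau_gaba, double tau_x, double tau_s,
    double alpha, double c_mg, int delay_steps,
    double bg_rate_ms,           // background events per ms per neuron
    NumericVector task_rate_ms,  // task events per ms per neuron
    double task_on_ms, double task_off_ms,
    int stim_mode,               // 0 none, 1 PS, 2 GS
    double stim_on_ms, double stim_off_ms,
    NumericVector istim_gs,      // pA per neuron (GS)
    NumericVector istim_cath,    // pA per neuron during cathodic phase (PS)
    double pulse_period_ms, double phase_ms,
    NumericVector tpp_full, NumericVector tps_full,
    double block_cap, bool block_on_total,
    double dt, int n_steps,
    bool refractory_clamp,
    IntegerVector rec_idx,       // 0-based neurons for current recording
    int rec_every)
{
  std::vector<double> V(n), s_ext(n, 0.0), s_arec(n, 0.0), x_nmda(n, 0.0),
      s_nmda(n, 0.0), s_gaba(n, 0.0), ref_clock(n, 0.0), tpp_clock(n, 0.0),
      tps_clock(n, 0.0), next_bg(n), next_task(n);
  std::vector<char> pending_tpp(n, 0);

  for (int i = 0; i < n; ++i) {
    V[i] = EL[i];
    next_bg[i] = bg_rate_ms > 0 ? R::rexp(1.0 / bg_rate_ms) : R_PosInf;
    next_task[i] = task_rate_ms[i] > 0
        ? task_on_ms + R::rexp(1.0 / task_rate_ms[i]) : R_PosInf;
  }

  // delayed recurrent spike queue (ring buffer over steps)
  int ring_len = delay_steps + 1;
  std::vector< std::vector<int> > ring(ring_len);

  std::vector<int> spk_neuron;
  std::vector<int> gated_pp(n, 0), gated_ps(n, 0);
  std::vector<double> spk_time;
  spk_neuron.reserve(4096);
  spk_time.reserve(4096);

  // stimulated neurons (anything with a nonzero coupling or refractory entry)
  std::vector<int> stim_set;
  if (stim_mode != 0) {
    for (int i = 0; i < n; ++i) {
      if (istim_gs[i] != 0.0 || istim_cath[i] != 0.0 ||
          tpp_full[i] > 0.0 || tps_full[i] > 0.0)
        stim_set.push_back(i);
    }
  }

  // current recording
  int n_rec = rec_idx.size();
  int n_samp = n_rec > 0 ? (n_steps + rec_every - 1) / rec_every : 0;
  NumericMatrix rec_ampa(n_rec, n_samp), rec_nmda(n_rec, n_samp),
      rec_gaba(n_rec, n_samp);
  NumericVector rec_t(n_samp);
  std::vector<int> rec_slot(n, -1);
  for (int k = 0; k < n_rec; ++k) rec_slot[rec_idx[k]] = k;

  double next_pulse = stim_on_ms;
  double footprint_end = -1.0;
  bool ftp_prev = false;

  double decay_ext = dt / tau_ampa, decay_gaba = dt / tau_gaba,
         decay_x = dt / tau_x;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    double t_next = t + dt;

    // ---- pulse bookkeeping -------------------------------------------
    bool ftp_now = false;
    bool cath_now = false, anod_now = false;
    if (stim_mode == 1 && t >= stim_on_ms && t < stim_off_ms) {
      double tt = t - stim_on_ms;
      double tp = tt - std::floor(tt / pulse_period_ms) * pulse_period_ms;
      cath_now = tp < phase_ms;
      anod_now = !cath_now && tp < 2.0 * phase_ms;
      ftp_now = cath_now || anod_now;
      if (t >= next_pulse - 1e-9 && next_pulse < stim_off_ms) {
        // pulse arrival
        for (size_t k = 0; k < stim_set.size(); ++k) {
          int i = stim_set[k];
          if (tpp_clock[i] > 0.0) {
            tpp_clock[i] = tpp_full[i] / 2.0;  // residual pulse-pulse block
          } else if (tpp_full[i] > 0.0) {
            pending_tpp[i] = 1;                // starts at footprint end
          }
        }
        footprint_end = next_pulse + 2.0 * phase_ms;
        next_pulse += pulse_period_ms;
      }
    }
    if (stim_mode == 1 && footprint_end > 0 && t >= footprint_end - 1e-9) {
      for (size_t k = 0; k < stim_set.size(); ++k) {
        int i = stim_set[k];
        if (pending_tpp[i]) {
          if (tpp_full[i] > tpp_clock[i]) tpp_clock[i] = tpp_full[i];
          pending_tpp[i] = 0;
        }
        if (tps_full[i] > tps_clock[i]) tps_clock[i] = tps_full[i];
      }
      footprint_end = -1.0;
    }
    bool pulse_recent = ftp_now || ftp_prev;
    ftp_prev = ftp_now;

    bool gs_on = stim_mode == 2 && t >= stim_on_ms && t < stim_off_ms;

    // ---- gating decay (forward Euler) --------------------------------
    for (int i = 0; i < n; ++i) {
      if (is_pyr[i]) {
        double x = x_nmda[i];
        s_ext[i] -= s_ext[i] * decay_ext;
        s_arec[i] -= s_arec[i] * decay_ext;
        x_nmda[i] = x - x * decay_x;
        s_nmda[i] += dt * (alpha * x * (1.0 - s_nmda[i]) - s_nmda[i] / tau_s);
      } else {
        s_ext[i] -= s_ext[i] * decay_ext;
        s_gaba[i] -= s_gaba[i] * decay_gaba;
      }
    }

    // ---- arrivals: delayed recurrent spikes, then external events ----
    std::vector<int>& due = ring[step % ring_len];
    for (size_t k = 0; k < due.size(); ++k) {
      int i = due[k];
      if (is_pyr[i]) { s_arec[i] += 1.0; x_nmda[i] += 1.0; }
      else s_gaba[i] += 1.0;
    }
    due.clear();

    for (int i = 0; i < n; ++i) {
      while (next_bg[i] <= t_next) {
        s_ext[i] += 1.0;
        next_bg[i] += R::rexp(1.0 / bg_rate_ms);
      }
      if (task_rate_ms[i] > 0 && t < task_off_ms) {
        while (next_task[i] <= t_next && next_task[i] <= task_off_ms) {
          s_ext[i] += 1.0;
          next_task[i] += R::rexp(1.0 / task_rate_ms[i]);
        }
      }
    }

    // ---- population aggregates ---------------------------------------
    double agg_a[4] = {0, 0, 0, 0}, agg_n[4] = {0, 0, 0, 0},
           agg_g[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      int p = pop[i];
      if (is_pyr[i]) { agg_a[p] += s_arec[i]; agg_n[p] += s_nmda[i]; }
      else agg_g[p] += s_gaba[i];
    }

    bool record_now = n_rec > 0 && (step % rec_every == 0);
    int samp = record_now ? step / rec_every : -1;
    if (record_now) rec_t[samp] = t;

    // ---- membrane update ---------------------------------------------
    for (int i = 0; i < n; ++i) {
      int p = pop[i];
      double wa = 0, wn = 0, wg = 0;
      for (int q = 0; q < 4; ++q) {
        double w = W(q, p);
        if (w != 0.0) { wa += w * agg_a[q]; wn += w * agg_n[q]; wg += w * agg_g[q]; }
      }
      double wself = W(p, p);
      if (wself != 0.0) {
        if (is_pyr[i]) { wa -= wself * s_arec[i]; wn -= wself * s_nmda[i]; }
        else wg -= wself * s_gaba[i];
      }
      double v = V[i];
      double i_ext = g_ext[i] * s_ext[i] * (E_ampa - v);
      double i_arec = g_arec[i] * wa * (E_ampa - v);
      double i_nmda = g_nmda[i] * wn * (E_nmda - v) /
                      (1.0 + c_mg * std::exp(-62.0 * v * 1e-3) / 3.57);
      double i_gaba = g_gaba[i] * wg * (E_gaba - v);
      double isyn = i_ext + i_arec + i_nmda + i_gaba;

      double istim = 0.0;
      if (gs_on) istim = istim_gs[i];
      else if (stim_mode == 1) {
        if (cath_now) istim = istim_cath[i];
        else if (anod_now) istim = -istim_cath[i];
      }

      if (gs_on && istim_gs[i] != 0.0) {
        double tested = block_on_total ? isyn + istim : istim;
        if (tested > block_cap) { isyn = 0.0; istim = 0.0; }
      }

      if (record_now && rec_slot[i] >= 0) {
        rec_ampa(rec_slot[i], samp) = i_arec;
        rec_nmda(rec_slot[i], samp) = i_nmda;
        rec_gaba(rec_slot[i], samp) = i_gaba;
      }

      if (ref_clock[i] > 0.0) {
        ref_clock[i] -= dt;
        if (refractory_clamp) {
          V[i] = Vr[i];
        } else {
          // pA / nF = 1 mV/s -> 1e-3 mV/ms
          v += dt * 1e-3 * (-gL[i] * (v - EL[i]) + isyn + istim) / Cm[i];
          V[i] = v > Vth[i] ? Vth[i] : v;
        }
      } else {
        v += dt * 1e-3 * (-gL[i] * (v - EL[i]) + isyn + istim) / Cm[i];
        if (!std::isfinite(v))
          stop("non-finite membrane potential at t=%f ms, neuron %d", t, i + 1);
        if (v > Vth[i]) {
          bool pulse_induced = stim_mode == 1 && pulse_recent &&
                               istim_cath[i] != 0.0;
          bool gated = pulse_induced ? tpp_clock[i] > 0.0
                                     : tps_clock[i] > 0.0;
          if (gated) {
            V[i] = Vth[i];  // AP not initiated; membrane otherwise free
            if (pulse_induced) ++gated_pp[i]; else ++gated_ps[i];
          } else {
            spk_neuron.push_back(i + 1);
            spk_time.push_back(t_next);
            V[i] = Vr[i];
            ref_clock[i] = tau_r[i];
            ring[(step + delay_steps) % ring_len].push_back(i);
          }
        } else {
          V[i] = v;
        }
      }

      if (tpp_clock[i] > 0.0) tpp_clock[i] -= dt;
      if (tps_clock[i] > 0.0) tps_clock[i] -= dt;
    }
  }

  List out = List::create(
      _["neuron_id"] = wrap(spk_neuron),
      _["t_ms"] = wrap(spk_time),
      _["gated_pulse"] = wrap(gated_pp),
      _["gated_spont"] = wrap(gated_ps));
  if (n_rec > 0) {
    out["rec_t_ms"] = rec_t;
    out["I_ampa_rec"] = rec_ampa;
    out["I_nmda"] = rec_nmda;
    out["I_gaba"] = rec_gaba;
  }
  return out;
}
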
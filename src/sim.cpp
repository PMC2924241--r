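// Core millisecond-resolution simulation loop for delayed spiking networks.
//
// Conventions (match the R-level documentation):
//   * time is an integer millisecond grid; spike i delivered on synapse s
//     arrives exactly delay[s] ms after emission (integer arithmetic);
//   * neuron and synapse indices arriving here are 0-based (converted at the
//     R boundary, where everything is 1-based);
//   * membrane dynamics are the two-variable quadratic model integrated with
//     two 0.5 ms substeps for v and one 1 ms step for u per grid step;
//   * inhibitory weights are stored negative; only synapses flagged plastic
//     (excitatory -> excitatory) are touched by any plasticity rule;
//   * all stochasticity draws from R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double SPIKE_PEAK = 30.0;

// [[Rcpp::export]]
List sim_core_cpp(int n,
                  NumericVector prm_a, NumericVector prm_b,
                  NumericVector prm_c, NumericVector prm_d,
                  NumericVector v0, NumericVector u0,
                  IntegerVector syn_pre, IntegerVector syn_post,
                  IntegerVector syn_delay,
                  NumericVector syn_w, NumericVector syn_sd,
                  LogicalVector syn_plastic,
                  int duration,
                  double mini_rate, double mini_amp,
                  IntegerVector stim_time, IntegerVector stim_neuron,
                  NumericVector stim_amp,
                  IntegerVector forced_time, IntegerVector forced_neuron,
                  bool lt_on, double lt_ap, double lt_am,
                  double lt_tp, double lt_tm, bool lt_nearest, double w_max,
                  int st_mode,   // 0 = off, 1 = short-term STDP, 2 = NMDA
                  double st_ap, double st_am, double st_tp, double st_tm,
                  double st_tau, double sd_min,
                  double nmda_tau, double theta_up, double theta_down,
                  double nmda_gain, double nmda_cap,
                  NumericVector gain_time, NumericVector lt_gain,
                  NumericVector st_gain,
                  IntegerVector sd_subset, int trace_dt) {
  const int m = syn_pre.size();
  int D = 1;
  for (int s = 0; s < m; ++s) {
    if (syn_delay[s] < 1) stop("synaptic delays must be positive integers");
    if (syn_delay[s] > D) D = syn_delay[s];
  }
  const int ring = D + 1;

  // efferent CSR (synapses must arrive sorted by presynaptic id)
  std::vector<int> eff_off(n + 1, 0);
  for (int s = 0; s < m; ++s) eff_off[syn_pre[s] + 1]++;
  for (int i = 0; i < n; ++i) eff_off[i + 1] += eff_off[i];
  for (int s = 1; s < m; ++s)
    if (syn_pre[s] < syn_pre[s - 1]) stop("synapses must be sorted by presynaptic id");

  // afferent CSR
  std::vector<int> aff_off(n + 1, 0), aff_idx(m);
  for (int s = 0; s < m; ++s) aff_off[syn_post[s] + 1]++;
  for (int i = 0; i < n; ++i) aff_off[i + 1] += aff_off[i];
  {
    std::vector<int> cur(aff_off.begin(), aff_off.end() - 1);
    for (int s = 0; s < m; ++s) aff_idx[cur[syn_post[s]]++] = s;
  }

  std::vector<double> v(v0.begin(), v0.end()), u(u0.begin(), u0.end());
  std::vector<double> w(syn_w.begin(), syn_w.end());
  std::vector<double> sd(syn_sd.begin(), syn_sd.end());
  std::vector<double> sd_t(m, 0.0);          // last short-term update time
  std::vector<double> pre_lt(m, 0.0), pre_st(m, 0.0), pre_t(m, -1e9);
  std::vector<double> post_lt(n, 0.0), post_st(n, 0.0), post_t(n, -1e9);
  std::vector<double> g(m, 0.0), g_t(m, 0.0), up_expire(m, -1.0);
  std::vector<char> up(m, 0);

  std::vector< std::vector<int> > sched(ring);
  std::vector<double> I(n, 0.0);
  std::vector<char> forced_now(n, 0);

  // membership mask for the sd-trace subset
  std::vector<char> in_subset(m, 0);
  for (int k = 0; k < sd_subset.size(); ++k) in_subset[sd_subset[k]] = 1;

  std::vector<int> sp_t, sp_i;
  sp_t.reserve(duration / 4 + 64);
  sp_i.reserve(duration / 4 + 64);
  std::vector<double> tr_time, tr_sub, tr_oth;

  const double p_mini = mini_rate / 1000.0;
  int stim_ptr = 0, forced_ptr = 0, gain_ptr = 0;
  double cur_lt_gain = 1.0, cur_st_gain = 1.0;

  RNGScope scope;

  for (int t = 0; t < duration; ++t) {
    // plasticity-rate schedule (step function, times ascending)
    while (gain_ptr < gain_time.size() && gain_time[gain_ptr] <= t) {
      cur_lt_gain = lt_gain[gain_ptr];
      cur_st_gain = st_gain[gain_ptr];
      ++gain_ptr;
    }

    std::fill(I.begin(), I.end(), 0.0);

    // (1) deliver presynaptic spikes arriving now
    std::vector<int> &slot = sched[t % ring];
    for (size_t k = 0; k < slot.size(); ++k) {
      const int s = slot[k];
      const int j = syn_post[s];
      double weff = w[s];
      if (syn_plastic[s]) {
        if (st_mode == 1) {
          const double sdv = sd[s] * std::exp(-(t - sd_t[s]) / st_tau);
          sd[s] = sdv; sd_t[s] = t;
          weff = w[s] * (1.0 + sdv);
        } else if (st_mode == 2) {
          // dendritic NMDA spike: 10-fold synaptic efficacy, but the somatic
          // impact of the plateau saturates
          if (up[s] && t < up_expire[s])
            weff = std::min(w[s] * nmda_gain, nmda_cap);
          else up[s] = 0;
        }
        // long-term depression: post spike preceded this arrival
        if (lt_on) {
          const double ptr = post_lt[j] * std::exp(-(t - post_t[j]) / lt_tm);
          double wn = w[s] - cur_lt_gain * lt_am * ptr;
          w[s] = wn < 0.0 ? 0.0 : (wn > w_max ? w_max : wn);
        }
        // short-term depression mirrors the long-term window on sd
        if (st_mode == 1) {
          const double ptr = post_st[j] * std::exp(-(t - post_t[j]) / st_tm);
          double sn = sd[s] - cur_st_gain * st_am * ptr;
          sd[s] = sn < sd_min ? sd_min : (sn > 1.0 ? 1.0 : sn);
        }
        // eligibility traces keyed to arrival times
        const double dec = std::exp(-(t - pre_t[s]) / lt_tp);
        const double dec_st = std::exp(-(t - pre_t[s]) / st_tp);
        pre_lt[s] = (lt_nearest ? 0.0 : pre_lt[s] * dec) + 1.0;
        pre_st[s] = pre_st[s] * dec_st + 1.0;
        pre_t[s] = t;
        if (st_mode == 2) {
          const double gv = g[s] * std::exp(-(t - g_t[s]) / nmda_tau) + 1.0;
          g[s] = gv; g_t[s] = t;
          if (up[s])  // arrivals during the up-state prolong it
            up_expire[s] = t + nmda_tau * std::log(gv / theta_down);
        }
      }
      I[j] += weff;
    }
    slot.clear();

    // (2) background minis: independent Poisson pulse per neuron
    if (p_mini > 0.0) {
      for (int j = 0; j < n; ++j)
        if (unif_rand() < p_mini) I[j] += mini_amp;
    }

    // (3) external stimulus currents
    while (stim_ptr < stim_time.size() && stim_time[stim_ptr] == t) {
      I[stim_neuron[stim_ptr]] += stim_amp[stim_ptr];
      ++stim_ptr;
    }

    // forced spikes (noise-free cascades, template anchors)
    bool any_forced = false;
    while (forced_ptr < forced_time.size() && forced_time[forced_ptr] == t) {
      forced_now[forced_neuron[forced_ptr]] = 1;
      any_forced = true;
      ++forced_ptr;
    }

    // (4) advance neuron dynamics, collect spikes
    for (int j = 0; j < n; ++j) {
      bool fired = false;
      if (forced_now[j]) {
        fired = true;
        if (any_forced) forced_now[j] = 0;
      } else {
        double vj = v[j], uj = u[j];
        const double Ij = I[j];
        vj += 0.5 * (0.04 * vj * vj + 5.0 * vj + 140.0 - uj + Ij);
        if (vj < SPIKE_PEAK)
          vj += 0.5 * (0.04 * vj * vj + 5.0 * vj + 140.0 - uj + Ij);
        uj += prm_a[j] * (prm_b[j] * vj - uj);
        if (!std::isfinite(vj) || !std::isfinite(uj))
          stop("neuron state became non-finite at t=%d ms (neuron %d); "
               "check input currents", t, j + 1);
        if (vj >= SPIKE_PEAK) { fired = true; u[j] = uj; }
        else { v[j] = vj; u[j] = uj; }
      }
      if (fired) {
        sp_t.push_back(t);
        sp_i.push_back(j);
        v[j] = prm_c[j];
        u[j] += prm_d[j];
        // schedule deliveries
        for (int s = eff_off[j]; s < eff_off[j + 1]; ++s)
          sched[(t + syn_delay[s]) % ring].push_back(s);
        // postsynaptic plasticity: potentiate afferents that arrived before
        const double pdec_lt = std::exp(-(t - post_t[j]) / lt_tm);
        const double pdec_st = std::exp(-(t - post_t[j]) / st_tm);
        post_lt[j] = post_lt[j] * pdec_lt + 1.0;
        post_st[j] = post_st[j] * pdec_st + 1.0;
        post_t[j] = t;
        for (int k = aff_off[j]; k < aff_off[j + 1]; ++k) {
          const int s = aff_idx[k];
          if (!syn_plastic[s]) continue;
          if (lt_on) {
            const double ptr = pre_lt[s] * std::exp(-(t - pre_t[s]) / lt_tp);
            double wn = w[s] + cur_lt_gain * lt_ap * ptr;
            w[s] = wn < 0.0 ? 0.0 : (wn > w_max ? w_max : wn);
          }
          if (st_mode == 1) {
            const double sdv = sd[s] * std::exp(-(t - sd_t[s]) / st_tau);
            const double ptr = pre_st[s] * std::exp(-(t - pre_t[s]) / st_tp);
            double sn = sdv + cur_st_gain * st_ap * ptr;
            sd[s] = sn < sd_min ? sd_min : (sn > 1.0 ? 1.0 : sn);
            sd_t[s] = t;
          } else if (st_mode == 2) {
            const double gv = g[s] * std::exp(-(t - g_t[s]) / nmda_tau);
            if (gv > theta_up) {
              up[s] = 1;
              up_expire[s] = t + nmda_tau * std::log(gv / theta_down);
            }
          }
        }
      }
    }

    // (5) short-term trace recording
    if (trace_dt > 0 && (t + 1) % trace_dt == 0) {
      double acc_sub = 0.0, acc_oth = 0.0;
      int n_sub = 0, n_oth = 0;
      for (int s = 0; s < m; ++s) {
        if (!syn_plastic[s]) continue;
        double val = 0.0;
        if (st_mode == 1)
          val = sd[s] * std::exp(-(t - sd_t[s]) / st_tau);
        else if (st_mode == 2)
          val = (up[s] && t < up_expire[s]) ? (nmda_gain - 1.0) : 0.0;
        if (in_subset[s]) { acc_sub += val; ++n_sub; }
        else              { acc_oth += val; ++n_oth; }
      }
      tr_time.push_back(t + 1);
      tr_sub.push_back(n_sub ? acc_sub / n_sub : NA_REAL);
      tr_oth.push_back(n_oth ? acc_oth / n_oth : NA_REAL);
    }
  }

  // decay short-term state to end-of-run so returned values share a time base
  const double tend = duration;
  for (int s = 0; s < m; ++s) {
    if (st_mode == 1) {
      sd[s] *= std::exp(-(tend - sd_t[s]) / st_tau);
      sd_t[s] = tend;
    } else if (st_mode == 2) {
      g[s] *= std::exp(-(tend - g_t[s]) / nmda_tau);
      g_t[s] = tend;
      if (up[s] && tend >= up_expire[s]) up[s] = 0;
    }
  }

  return List::create(
    _["spike_time"] = wrap(sp_t),
    _["spike_neuron"] = wrap(sp_i),
    _["w"] = wrap(w),
    _["sd"] = wrap(sd),
    _["nmda_g"] = wrap(g),
    _["nmda_up"] = LogicalVector(up.begin(), up.end()),
    _["v"] = wrap(v),
    _["u"] = wrap(u),
    _["trace_time"] = wrap(tr_time),
    _["trace_subset"] = wrap(tr_sub),
    _["trace_other"] = wrap(tr_oth));
}
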
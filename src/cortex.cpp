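#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Leaky integrate-and-fire sheet with conductance-free exponential synaptic
// currents and pair-based additive STDP restricted to excitatory->excitatory
// synapses (recurrent and afferent).  Receptor channels inject Poisson
// spike trains whose rate follows a piecewise-constant frame sequence.
//
// All indices passed from R are 0-based.
//
// [[Rcpp::export]]
List cortex_run_cpp(int n, LogicalVector is_exc,
                    IntegerVector out_ptr, IntegerVector out_syn,
                    IntegerVector syn_dst,
                    IntegerVector in_ptr, IntegerVector in_syn,
                    IntegerVector syn_src,
                    NumericVector w_in_, LogicalVector syn_plastic,
                    IntegerVector chan_ptr, IntegerVector chan_tgt,
                    NumericVector win_in_, LogicalVector win_plastic,
                    IntegerVector ntgt_ptr, IntegerVector ntgt_idx,
                    IntegerVector ntgt_chan,
                    NumericMatrix rates, int frame_steps,
                    List lif, List stdp, bool stdp_on,
                    double noise_rate, NumericVector noise_amp,
                    NumericVector i_const,
                    int n_steps, double dt, int seed,
                    bool record_spikes, int vmean_every,
                    int norm_every) {
  const double tau_m = as<double>(lif["tau_m"]);
  const double v_rest = as<double>(lif["v_rest"]);
  const double v_th = as<double>(lif["v_thresh"]);
  const double v_reset = as<double>(lif["v_reset"]);
  const int t_ref = (int)std::lround(as<double>(lif["refractory"]) / dt);
  const double tau_e = as<double>(lif["tau_syn_e"]);
  const double tau_i = as<double>(lif["tau_syn_i"]);
  const double dec_e = std::exp(-dt / tau_e);
  const double dec_i = std::exp(-dt / tau_i);

  const double A_plus = as<double>(stdp["A_plus"]);
  const double A_minus = as<double>(stdp["A_minus"]);
  const double dec_p = std::exp(-dt / as<double>(stdp["tau_plus"]));
  const double dec_m = std::exp(-dt / as<double>(stdp["tau_minus"]));
  const double w_max = as<double>(stdp["w_max"]);
  // afferent (receptor->cortex) synapses may use their own pair
  // amplitudes and cap
  const double ap_in = as<double>(stdp["A_plus_in"]);
  const double am_in = as<double>(stdp["A_minus_in"]);
  const double wmax_in = as<double>(stdp["w_max_in"]);

  const int nchan = rates.nrow();
  const int nframes = rates.ncol();

  NumericVector w = clone(w_in_);
  NumericVector win = clone(win_in_);

  std::vector<double> V(n, v_rest), ge(n, 0.0), gi(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<double> tr_pre(n, 0.0), tr_post(n, 0.0), tr_chan(nchan, 0.0);
  std::vector<double> p_noise(1, 0.0);
  std::vector<int> spk_count(n, 0);

  // synaptic scaling reference: initial total plastic afferent weight
  // per postsynaptic neuron
  std::vector<double> win_sum0(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = ntgt_ptr[i]; k < ntgt_ptr[i + 1]; ++k)
      if (win_plastic[ntgt_idx[k]]) win_sum0[i] += win[ntgt_idx[k]];

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  std::vector<double> vmean, vmean_active;
  std::vector<int> fired; fired.reserve(256);

  const double pnz = noise_rate * dt;

  for (int step = 0; step < n_steps; ++step) {
    int frame = std::min(step / frame_steps, nframes - 1);
    // --- channel input spikes ---
    for (int c = 0; c < nchan; ++c) {
      tr_chan[c] *= dec_p;
      double pr = rates(c, frame) * dt;
      if (pr > 0.0 && unif(rng) < pr) {
        tr_chan[c] += 1.0;
        for (int k = chan_ptr[c]; k < chan_ptr[c + 1]; ++k) {
          int tgt = chan_tgt[k];
          ge[tgt] += win[k];
          if (stdp_on && win_plastic[k]) {
            win[k] -= am_in * tr_post[tgt];
            if (win[k] < 0.0) win[k] = 0.0;
          }
        }
      }
    }
    // --- decay synaptic currents and plasticity traces ---
    for (int i = 0; i < n; ++i) {
      tr_pre[i] *= dec_p; tr_post[i] *= dec_m;
      ge[i] *= dec_e; gi[i] *= dec_i;
    }
    // --- background noise: binomial thinning instead of per-neuron draws
    if (pnz > 0.0) {
      std::binomial_distribution<int> nb(n, pnz);
      int k = nb(rng);
      for (int e = 0; e < k; ++e) { int i = pick(rng); ge[i] += noise_amp[i]; }
    }
    // --- membrane update ---
    fired.clear();
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0) { refr[i]--; continue; }
      V[i] += dt * ((v_rest - V[i]) / tau_m + ge[i] - gi[i] + i_const[i]);
      if (V[i] >= v_th) {
        V[i] = v_reset; refr[i] = t_ref;
        fired.push_back(i);
      }
    }
    // --- spike propagation + STDP ---
    for (size_t f = 0; f < fired.size(); ++f) {
      int i = fired[f];
      spk_count[i]++;
      if (record_spikes) { spike_t.push_back(step * dt); spike_id.push_back(i); }
      bool exc = is_exc[i];
      if (exc) tr_pre[i] += 1.0;
      tr_post[i] += 1.0;
      // outgoing
      for (int k = out_ptr[i]; k < out_ptr[i + 1]; ++k) {
        int s = out_syn[k];
        int dst = syn_dst[s];
        if (exc) {
          ge[dst] += w[s];
          if (stdp_on && syn_plastic[s]) {
            w[s] -= A_minus * tr_post[dst];
            if (w[s] < 0.0) w[s] = 0.0;
          }
        } else {
          gi[dst] += w[s];
        }
      }
      if (stdp_on && exc) {
        // potentiate incoming plastic recurrent synapses
        for (int k = in_ptr[i]; k < in_ptr[i + 1]; ++k) {
          int s = in_syn[k];
          if (syn_plastic[s]) {
            w[s] += A_plus * tr_pre[syn_src[s]];
            if (w[s] > w_max) w[s] = w_max;
          }
        }
        // potentiate incoming plastic afferent (channel) synapses
        for (int k = ntgt_ptr[i]; k < ntgt_ptr[i + 1]; ++k) {
          int kk = ntgt_idx[k];
          if (win_plastic[kk]) {
            win[kk] += ap_in * tr_chan[ntgt_chan[k]];
            if (win[kk] > wmax_in) win[kk] = wmax_in;
          }
        }
      }
    }
    // homeostatic synaptic scaling of afferent weights (multiplicative)
    if (stdp_on && norm_every > 0 && (step + 1) % norm_every == 0) {
      for (int i = 0; i < n; ++i) {
        if (win_sum0[i] <= 0.0) continue;
        double s_now = 0.0;
        for (int k = ntgt_ptr[i]; k < ntgt_ptr[i + 1]; ++k)
          if (win_plastic[ntgt_idx[k]]) s_now += win[ntgt_idx[k]];
        if (s_now > 0.0) {
          double f = win_sum0[i] / s_now;
          for (int k = ntgt_ptr[i]; k < ntgt_ptr[i + 1]; ++k)
            if (win_plastic[ntgt_idx[k]]) win[ntgt_idx[k]] *= f;
        }
      }
    }
    if (vmean_every > 0 && step % vmean_every == 0) {
      double sv = 0.0; for (int i = 0; i < n; ++i) sv += V[i];
      vmean.push_back(sv / n);
    }
    if (!R_finite(V[0]))
      stop("cortex membrane potential diverged at step %d", step + 1);
  }

  NumericVector rates_out(n);
  for (int i = 0; i < n; ++i) rates_out[i] = spk_count[i] / (n_steps * dt);

  return List::create(
      _["w"] = w, _["w_in"] = win,
      _["rates"] = rates_out,
      _["spike_t"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["n_spikes"] = (double)std::accumulate(spk_count.begin(),
                                              spk_count.end(), 0),
      _["v_mean"] = NumericVector(vmean.begin(), vmean.end()),
      _["counts"] = IntegerVector(spk_count.begin(), spk_count.end()));
}
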
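// Conductance-based leaky integrate-and-fire network with AMPA (external
// and recurrent), NMDA and GABA synapses, five populations, full
// connectivity with block-structured weights and no synaptic delay.
//
// Because weights only depend on the (source pool, target pool) pair, the
// recurrent input to a neuron reduces to pool-level sums of the presynaptic
// gating variables; the per-step cost is O(N), not O(N^2).
//
// Units: mV, ms, nF, nS.  A current expressed as conductance [nS] times
// driving force [mV] is in pA, and pA / nF = mV/s, so the membrane update
// is dV = -(dt * 1e-3) * I / Cm with dt in ms.
//
// External input: each neuron receives one aggregated Poisson process with
// rate N_ext * (background + pool stimulus) Hz, realised by drawing the
// pooled event count per population per step and scattering events
// uniformly over the pool's neurons (statistically identical to
// independent per-source generators).
//
// Uses R's RNG so that set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_lif_run")]]
List cpp_lif_run(IntegerVector pool_sizes,      // length 5: L R S NS I
                 NumericMatrix W,               // 5x5 source pool x target pool
                 List neuron,                   // per-class parameters
                 NumericMatrix ext_rate,        // n_steps x 5, total Hz per neuron
                 double dt,                     // ms
                 double t0,                     // ms, time at state_in
                 List state_in,                 // state vectors or empty list
                 bool record_spikes = true) {
  const int n_pools = 5;
  int N = 0;
  std::vector<int> start(n_pools + 1, 0);
  for (int p = 0; p < n_pools; ++p) {
    start[p + 1] = start[p] + pool_sizes[p];
    N += pool_sizes[p];
  }
  const int n_steps = ext_rate.nrow();

  // per-class (excitatory = pools 0..3, inhibitory = pool 4) parameters
  auto gp = [&](const char* nm) { return as<NumericVector>(neuron[nm]); };
  NumericVector Cm = gp("Cm"), gL = gp("gL"), trp = gp("tau_rp");
  NumericVector gae = gp("g_ampa_ext"), gar = gp("g_ampa_rec");
  NumericVector gn = gp("g_nmda"), gg = gp("g_gaba");
  const double VL = neuron["V_L"], VE = neuron["V_E"], VI = neuron["V_I"];
  const double Vthr = neuron["V_thr"], Vreset = neuron["V_reset"];
  const double tau_ampa = neuron["tau_ampa"], tau_gaba = neuron["tau_gaba"];
  const double tau_nr = neuron["tau_nmda_rise"], tau_nd = neuron["tau_nmda_decay"];
  const double alpha = neuron["alpha"];  // 1/ms
  const double mg = neuron["mg"];

  const double dec_a = std::exp(-dt / tau_ampa);
  const double dec_g = std::exp(-dt / tau_gaba);
  const double dec_x = std::exp(-dt / tau_nr);

  std::vector<double> V(N, VL), s_ext(N, 0.0), s_ar(N, 0.0), s_n(N, 0.0),
      x_n(N, 0.0), s_g(N, 0.0), t_last(N, -1e9);
  if (state_in.size() > 0) {
    NumericVector v = state_in["V"], a = state_in["s_ampa_ext"],
                  b = state_in["s_ampa_rec"], c = state_in["s_nmda"],
                  d = state_in["x_nmda"], e = state_in["s_gaba"],
                  f = state_in["t_last_spike"];
    for (int i = 0; i < N; ++i) {
      V[i] = v[i]; s_ext[i] = a[i]; s_ar[i] = b[i]; s_n[i] = c[i];
      x_n[i] = d[i]; s_g[i] = e[i]; t_last[i] = f[i];
    }
  }

  std::vector<int> sp_id; std::vector<double> sp_t;
  std::vector<int> fired; fired.reserve(64);

  double S_ar[5], S_n[5], S_g;
  for (int step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;
    // pool sums of presynaptic gating (state at start of step)
    S_g = 0.0;
    for (int p = 0; p < 4; ++p) {
      double sa = 0.0, sn = 0.0;
      for (int i = start[p]; i < start[p + 1]; ++i) { sa += s_ar[i]; sn += s_n[i]; }
      S_ar[p] = sa; S_n[p] = sn;
    }
    for (int i = start[4]; i < start[5]; ++i) S_g += s_g[i];

    fired.clear();
    for (int p = 0; p < n_pools; ++p) {
      const int cls = (p < 4) ? 0 : 1;
      const double wLL = W(0, p), wRR = W(1, p), wSS = W(2, p), wNN = W(3, p);
      const double drv_a0 = wLL * S_ar[0] + wRR * S_ar[1] + wSS * S_ar[2] +
                            wNN * S_ar[3];
      const double drv_n0 = wLL * S_n[0] + wRR * S_n[1] + wSS * S_n[2] +
                            wNN * S_n[3];
      const double w_self = (p < 4) ? W(p, p) : 0.0;
      for (int i = start[p]; i < start[p + 1]; ++i) {
        const double v = V[i];
        const bool refr = (t - t_last[i]) < trp[cls];
        if (!refr) {
          // exclude the neuron's own presynaptic gating (no autapses)
          double da = drv_a0, dn = drv_n0, dgb = S_g;
          if (p < 4) { da -= w_self * s_ar[i]; dn -= w_self * s_n[i]; }
          else dgb -= s_g[i];
          const double gate = 1.0 / (1.0 + mg * std::exp(-0.062 * v) / 3.57);
          double I = gL[cls] * (v - VL) +
                     gae[cls] * (v - VE) * s_ext[i] +
                     gar[cls] * (v - VE) * da +
                     gn[cls] * (v - VE) * gate * dn +
                     gg[cls] * (v - VI) * dgb;
          V[i] = v - dt * 1e-3 * I / Cm[cls];  // pA / nF = mV/s
          if (!std::isfinite(V[i]))
            stop("non-finite membrane potential at t = %f ms (neuron %d)",
                 t, i + 1);
        } else {
          V[i] = Vreset;
        }
        // gating decay (exact for the exponential kinetics)
        s_ext[i] *= dec_a;
        s_ar[i] *= dec_a;
        s_g[i] *= dec_g;
        s_n[i] += dt * (-s_n[i] / tau_nd + alpha * x_n[i] * (1.0 - s_n[i]));
        x_n[i] *= dec_x;
        if (!refr && V[i] >= Vthr) {
          // linear interpolation of the crossing time within the step
          // removes the leading-order overshoot bias of the Euler step
          double frac = (V[i] > v) ? (Vthr - v) / (V[i] - v) : 1.0;
          if (frac < 0.0) frac = 0.0;
          if (frac > 1.0) frac = 1.0;
          double ts = t + frac * dt;
          t_last[i] = ts;
          V[i] = Vreset;
          fired.push_back(i);
          if (record_spikes) { sp_id.push_back(i + 1); sp_t.push_back(ts); }
        }
      }
    }
    // presynaptic increments from this step's spikes (affect next step)
    for (int i : fired) {
      if (i < start[4]) { s_ar[i] += 1.0; x_n[i] += 1.0; }
      else s_g[i] += 1.0;
    }
    // external Poisson events, pooled per population then scattered
    for (int p = 0; p < n_pools; ++p) {
      const int np = pool_sizes[p];
      if (np == 0) continue;
      const double lam = np * ext_rate(step, p) * dt * 1e-3;  // Hz * ms
      const int k = (int)R::rpois(lam);
      for (int e = 0; e < k; ++e) {
        int i = start[p] + (int)(unif_rand() * np);
        if (i >= start[p + 1]) i = start[p + 1] - 1;
        s_ext[i] += 1.0;
      }
    }
  }

  List state_out = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["s_ampa_ext"] = NumericVector(s_ext.begin(), s_ext.end()),
      _["s_ampa_rec"] = NumericVector(s_ar.begin(), s_ar.end()),
      _["s_nmda"] = NumericVector(s_n.begin(), s_n.end()),
      _["x_nmda"] = NumericVector(x_n.begin(), x_n.end()),
      _["s_gaba"] = NumericVector(s_g.begin(), s_g.end()),
      _["t_last_spike"] = NumericVector(t_last.begin(), t_last.end()),
      _["t"] = t0 + n_steps * dt);
  return List::create(
      _["spike_neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["state"] = state_out);
}
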
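#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

// The synaptic gate traces decay exponentially toward zero and spend most of
// their time at very small magnitudes; letting them enter the subnormal
// range stalls the FPU by two orders of magnitude.  Flush-to-zero is
// numerically harmless here (gates below ~1e-300 are physically zero).
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int saved_csr;
  FlushDenormals() : saved_csr(_mm_getcsr()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() { _mm_setcsr(saved_csr); }
#endif
};

// Conductance-based LIF excitatory/inhibitory network.
//
// Membrane:  tau_m dV/dt = -(V - v_rest) + I_tot / g_leak,  V in absolute mV.
// Synapses:  I_c = -g_c s_c (V - Vrev_c) for c in {GABA, AMPA_rec, AMPA_ext};
//            each presynaptic spike at t* adds, after latency tau_l,
//            s(t) += tau_m/(tau_d - tau_r) [exp(-(t-tau_l-t*)/tau_d)
//                                         - exp(-(t-tau_l-t*)/tau_r)],
//            implemented as a pair of exponential traces (xd, xr) with exact
//            per-step decay and unit increments at delivery time.
// Integration: second-order Runge-Kutta (Heun) at fixed dt; gates are
// advanced exactly, the membrane uses gate values at both step ends.
//
// External drive: either an explicit spike list (neuron, time) or a per-step
// rate (sp/s) thinned to Bernoulli(nu*dt) per neuron under R's RNG.

// [[Rcpp::export(name = ".sim_lif_network")]]
List sim_lif_network(int n_exc, int n_inh,
                     IntegerVector adj_targets, IntegerVector adj_offsets,
                     NumericMatrix syn,      // 6 x 4 (g, tau_l, tau_r, tau_d)
                     NumericVector v_rev,    // GABA, AMPA_rec, AMPA_ext (mV)
                     NumericVector tau_m, NumericVector g_leak,
                     NumericVector v_rest, NumericVector v_thr,
                     NumericVector v_reset, NumericVector refr_ms,
                     double dt, int n_steps, int discard_steps,
                     NumericVector ext_rate,
                     IntegerVector ext_neuron, NumericVector ext_time_ms,
                     NumericVector v_init) {
  FlushDenormals ftz_guard;
  const int N = n_exc + n_inh;
  if (N <= 0) stop("network must contain at least one neuron");
  if (dt <= 0) stop("dt must be positive");
  if (adj_offsets.size() != N + 1)
    stop("adjacency offsets must have length N+1");

  // per (class, population) kinetic constants; row = class*2 + pop
  double g[3][2], coef[3][2], fd[3][2], fr[3][2];
  int delay_steps[3];
  for (int c = 0; c < 3; ++c) {
    for (int p = 0; p < 2; ++p) {
      const int row = c * 2 + p;
      const double tr = syn(row, 2), td = syn(row, 3);
      if (!(td > tr) || tr <= 0)
        stop("synaptic kinetics require tau_d > tau_r > 0");
      g[c][p]    = syn(row, 0);
      coef[c][p] = tau_m[p] / (td - tr);
      fd[c][p]   = std::exp(-dt / td);
      fr[c][p]   = std::exp(-dt / tr);
    }
    if (std::abs(syn(c * 2, 1) - syn(c * 2 + 1, 1)) > 1e-12)
      stop("synaptic latency must not depend on the target population");
    delay_steps[c] = (int)std::lround(syn(c * 2, 1) / dt);
    if (delay_steps[c] < 0) stop("negative synaptic latency");
  }
  const int refr_steps[2] = {(int)std::lround(refr_ms[0] / dt),
                             (int)std::lround(refr_ms[1] / dt)};

  // state
  std::vector<double> V(N);
  if (v_init.size() == N) {
    for (int k = 0; k < N; ++k) V[k] = v_init[k];
  } else {
    for (int k = 0; k < N; ++k) {
      const int p = (k < n_exc) ? 0 : 1;
      V[k] = v_rest[p] + unif_rand() * (v_thr[p] - v_rest[p]);
    }
  }
  std::vector<int> refr(N, 0);
  std::vector<double> xd0(N, 0.0), xr0(N, 0.0), xd1(N, 0.0), xr1(N, 0.0),
      xd2(N, 0.0), xr2(N, 0.0);

  // delay rings: slot = step % L holds arrivals due at that step
  const int L = std::max(std::max(delay_steps[0], delay_steps[1]),
                         delay_steps[2]) + 2;
  std::vector<std::vector<int>> ring_exc(L), ring_inh(L), ring_ext(L);

  // explicit external spikes, sorted by time in the R wrapper
  const bool rate_mode = ext_rate.size() > 0;
  if (rate_mode && ext_rate.size() != n_steps)
    stop("external rate must provide one value per time step");
  int ext_ptr = 0;
  const int n_ext = ext_neuron.size();

  // shuffled-index pool for Bernoulli thinning
  std::vector<int> pool(N);
  for (int k = 0; k < N; ++k) pool[k] = k;

  const int kept = n_steps - discard_steps;
  if (kept <= 0) stop("simulation shorter than the discarded transient");
  NumericVector cur_gaba(kept), cur_ampar(kept), cur_ampae(kept);
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  sp_id.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  for (int n = 0; n < n_steps; ++n) {
    const int slot = n % L;
    // deliver recurrent arrivals
    for (int j : ring_inh[slot]) {
      for (int a = adj_offsets[j]; a < adj_offsets[j + 1]; ++a) {
        const int k = adj_targets[a];
        xd0[k] += 1.0; xr0[k] += 1.0;
      }
    }
    ring_inh[slot].clear();
    for (int j : ring_exc[slot]) {
      for (int a = adj_offsets[j]; a < adj_offsets[j + 1]; ++a) {
        const int k = adj_targets[a];
        xd1[k] += 1.0; xr1[k] += 1.0;
      }
    }
    ring_exc[slot].clear();
    for (int k : ring_ext[slot]) { xd2[k] += 1.0; xr2[k] += 1.0; }
    ring_ext[slot].clear();

    // schedule external arrivals generated in this step
    if (rate_mode) {
      double p = ext_rate[n] * dt * 1e-3;
      if (p > 0) {
        if (p > 1) p = 1;
        const int m = (int)R::rbinom((double)N, p);
        const int dslot = (n + delay_steps[2]) % L;
        for (int i = 0; i < m; ++i) {
          const int j = i + (int)(unif_rand() * (N - i));
          std::swap(pool[i], pool[j >= N ? N - 1 : j]);
          ring_ext[dslot].push_back(pool[i]);
        }
      }
    } else {
      const double t_hi = (n + 0.5) * dt;
      while (ext_ptr < n_ext && ext_time_ms[ext_ptr] < t_hi) {
        const int due = n + delay_steps[2];
        if (due < n_steps + L)
          ring_ext[due % L].push_back(ext_neuron[ext_ptr]);
        ++ext_ptr;
      }
    }

    double sum_gaba = 0.0, sum_ampar = 0.0, sum_ampae = 0.0;

    for (int pop = 0; pop < 2; ++pop) {
      const int k0 = (pop == 0) ? 0 : n_exc;
      const int k1 = (pop == 0) ? n_exc : N;
      const double c0 = coef[0][pop], c1 = coef[1][pop], c2 = coef[2][pop];
      const double fd0 = fd[0][pop], fr0 = fr[0][pop];
      const double fd1 = fd[1][pop], fr1 = fr[1][pop];
      const double fd2 = fd[2][pop], fr2 = fr[2][pop];
      const double g0 = g[0][pop], g1 = g[1][pop], g2 = g[2][pop];
      const double vre = v_rest[pop], vth = v_thr[pop], vrs = v_reset[pop];
      const double gl = g_leak[pop], itm = 1.0 / tau_m[pop];
      const double e0 = v_rev[0], e1 = v_rev[1], e2 = v_rev[2];
      const int rsteps = refr_steps[pop];

      for (int k = k0; k < k1; ++k) {
        // gate values at step start
        const double s0a = c0 * (xd0[k] - xr0[k]);
        const double s1a = c1 * (xd1[k] - xr1[k]);
        const double s2a = c2 * (xd2[k] - xr2[k]);
        // exact gate decay to step end
        xd0[k] *= fd0; xr0[k] *= fr0;
        xd1[k] *= fd1; xr1[k] *= fr1;
        xd2[k] *= fd2; xr2[k] *= fr2;
        const double s0b = c0 * (xd0[k] - xr0[k]);
        const double s1b = c1 * (xd1[k] - xr1[k]);
        const double s2b = c2 * (xd2[k] - xr2[k]);

        double v = V[k];
        if (refr[k] > 0) {
          --refr[k];
          v = vrs;
        } else {
          // RK2 (Heun): f(V,s) = (-(V - v_rest) + I_tot/g_leak)/tau_m,
          // I_tot = -sum_c g_c s_c (V - Vrev_c)
          const double i1 = -(g0 * s0a * (v - e0) + g1 * s1a * (v - e1) +
                              g2 * s2a * (v - e2));
          const double f1 = (-(v - vre) + i1 / gl) * itm;
          const double vm = v + dt * f1;
          const double i2 = -(g0 * s0b * (vm - e0) + g1 * s1b * (vm - e1) +
                              g2 * s2b * (vm - e2));
          const double f2 = (-(vm - vre) + i2 / gl) * itm;
          v += 0.5 * dt * (f1 + f2);
          if (!R_FINITE(v))
            stop("membrane potential diverged at step %d (t = %.3f ms), neuron %d",
                 n + 1, (n + 1) * dt, k + 1);
          if (v >= vth) {
            sp_id.push_back(k + 1);
            sp_t.push_back((n + 1) * dt);
            v = vrs;
            refr[k] = rsteps;
            const int dly = (pop == 0) ? delay_steps[1] : delay_steps[0];
            std::vector<std::vector<int>>& ring =
                (pop == 0) ? ring_exc : ring_inh;
            ring[(n + 1 + dly) % L].push_back(k);
          }
        }
        V[k] = v;

        if (pop == 0 && n >= discard_steps) {
          sum_gaba  += g0 * s0b * (v - e0);
          sum_ampar += g1 * s1b * (v - e1);
          sum_ampae += g2 * s2b * (v - e2);
        }
      }
    }

    if (n >= discard_steps) {
      const int idx = n - discard_steps;
      // physical input currents: I = -g s (V - Vrev)
      cur_gaba[idx]  = -sum_gaba;
      cur_ampar[idx] = -sum_ampar;
      cur_ampae[idx] = -sum_ampae;
    }
    if ((n & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["i_gaba"] = cur_gaba, _["i_ampa_rec"] = cur_ampar,
      _["i_ampa_ext"] = cur_ampae,
      _["t_start_ms"] = (discard_steps + 1) * dt, _["dt"] = dt);
}
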
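// Network integrator for the CA3 microcircuit model.
//
// Fixed-step semi-implicit scheme (dt typically 0.025 ms): gating variables
// advance by exponential Euler using voltage-indexed lookup tables of
// (x_inf, 1 - exp(-dt/tau)); the membrane equation is solved implicitly in
// the local voltage with channel/synaptic conductances and axial neighbour
// voltages held at their current values. Double-exponential synapses use the
// standard two-state (rise/decay) linear formulation so events superpose.
//
// All randomness (background Poisson streams, nothing else) lives in
// per-stream counter-seeded splitmix64 generators, so each cell's event
// stream depends only on (master seed, stream id) — adding or removing other
// cells never perturbs it, and control/scaled paired runs share event times
// exactly.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0,1]
  double runif_oc() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }
  double rexp(double mean) { return -mean * std::log(runif_oc()); }
};

inline uint64_t stream_seed(uint64_t master, uint64_t id) {
  SplitMix g(master ^ (0xA0761D6478BD642FULL * (id + 1)));
  g.next();
  return g.next();
}

struct Gate {
  std::vector<double> minf, edt;  // indexed by voltage grid
  int expn;
  std::vector<double> x;  // state per channel-compartment
};

struct Channel {
  std::vector<int> comps;      // compartment indices (0-based)
  std::vector<double> gbar;    // nS per compartment
  double erev;
  std::vector<Gate> gates;
  bool ca_source;              // contributes to the Ca pool
  bool ca_gated;               // conductance multiplied by ca/(ca+kd)
  double kd;
};

}  // namespace

// Arguments, in blocks: compartments (capacitance nF, initial voltage, axial
// edges in nS); channels (list of list(comps, gbar, erev, gates = list(minf,
// edt, expn), ca_source, ca_gated, kd)) with the voltage-grid description;
// Ca-pool compartments and parameters; lumped double-exponential synapses;
// soma compartment + spike threshold/refractory per cell; network edges in
// CSR layout over presynaptic cells; background Poisson streams; the
// medial-septum pacemaker; scheduled synaptic events; current-injection
// windows; run control; recording (LFP compartment pairs, coarse and fine
// probes).
// [[Rcpp::export]]
List cpp_run_network(
    NumericVector cap_nF, NumericVector v_init,
    IntegerVector ax_i, IntegerVector ax_j, NumericVector ax_g,
    List channels_in,
    double vmin, double dv, int ntab,
    IntegerVector ca_comps, double ca_rest, double ca_tau, double ca_in,
    NumericVector ca_area_cm2,
    IntegerVector syn_comp, NumericVector syn_E,
    NumericVector syn_tau1, NumericVector syn_tau2,
    IntegerVector syn_mg, double mg_eta, double mg_gamma,
    IntegerVector soma_comp, double thresh, int refrac_steps,
    IntegerVector edge_ptr, IntegerVector edge_syn,
    NumericVector edge_w, IntegerVector edge_delay,
    IntegerVector bg_syn, NumericVector bg_rate_ms, NumericVector bg_w,
    NumericVector bg_sid,
    IntegerVector ms_syn, NumericVector ms_w, double ms_period_ms,
    NumericVector ev_t, IntegerVector ev_syn, NumericVector ev_w,
    IntegerVector inj_comp, NumericVector inj_nA,
    NumericVector inj_t0, NumericVector inj_t1,
    double dt, double duration, double master_seed,
    IntegerVector lfp_a3, IntegerVector lfp_bd, int rec_stride,
    IntegerVector rec_comps, IntegerVector fine_comps) {
  const int ncomp = cap_nF.size();
  const int ncell = soma_comp.size();
  const int nsyn = syn_comp.size();
  const int nsteps = (int)std::llround(duration / dt);

  // --- channels -------------------------------------------------------------
  std::vector<Channel> chans;
  for (int c = 0; c < channels_in.size(); ++c) {
    List ch = channels_in[c];
    Channel C;
    C.comps = as<std::vector<int>>(ch["comps"]);
    C.gbar = as<std::vector<double>>(ch["gbar"]);
    C.erev = as<double>(ch["erev"]);
    C.ca_source = as<bool>(ch["ca_source"]);
    C.ca_gated = as<bool>(ch["ca_gated"]);
    C.kd = as<double>(ch["kd"]);
    List gs = ch["gates"];
    for (int g = 0; g < gs.size(); ++g) {
      List gg = gs[g];
      Gate G;
      G.minf = as<std::vector<double>>(gg["minf"]);
      G.edt = as<std::vector<double>>(gg["edt"]);
      G.expn = as<int>(gg["expn"]);
      G.x.resize(C.comps.size());
      C.gates.push_back(std::move(G));
    }
    chans.push_back(std::move(C));
  }

  std::vector<double> V(v_init.begin(), v_init.end());

  auto tab_idx = [&](double v) {
    double u = (v - vmin) / dv;
    if (u < 0) u = 0;
    if (u > ntab - 2) u = ntab - 2;
    return u;
  };
  // initialise gates at steady state for v_init
  for (auto& C : chans)
    for (auto& G : C.gates)
      for (size_t k = 0; k < C.comps.size(); ++k) {
        double u = tab_idx(V[C.comps[k]]);
        int i = (int)u;
        double f = u - i;
        G.x[k] = G.minf[i] * (1 - f) + G.minf[i + 1] * f;
      }

  // --- Ca pools -------------------------------------------------------------
  std::vector<double> ca_of_comp(ncomp, -1.0);
  std::vector<double> ca(ca_comps.size(), ca_rest);
  for (int k = 0; k < ca_comps.size(); ++k) ca_of_comp[ca_comps[k]] = k;

  // --- synapses -------------------------------------------------------------
  std::vector<double> sA(nsyn, 0.0), sB(nsyn, 0.0);
  std::vector<double> d1(nsyn), d2(nsyn), sN(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    double t1 = syn_tau1[s], t2 = syn_tau2[s];
    d1[s] = std::exp(-dt / t1);
    d2[s] = std::exp(-dt / t2);
    double tp = t1 * t2 / (t2 - t1) * std::log(t2 / t1);
    sN[s] = 1.0 / (std::exp(-tp / t2) - std::exp(-tp / t1));
  }

  // --- axial ----------------------------------------------------------------
  // store per-compartment adjacency (neighbour, g)
  std::vector<std::vector<std::pair<int, double>>> adj(ncomp);
  for (int e = 0; e < ax_i.size(); ++e) {
    adj[ax_i[e]].push_back({ax_j[e], ax_g[e]});
    adj[ax_j[e]].push_back({ax_i[e], ax_g[e]});
  }

  // --- event queue ----------------------------------------------------------
  int maxdel = 1;
  for (int e = 0; e < edge_delay.size(); ++e)
    if (edge_delay[e] + 1 > maxdel) maxdel = edge_delay[e] + 1;
  const int qlen = maxdel + 1;
  std::vector<std::vector<std::pair<int, double>>> queue(qlen);

  // scheduled external events: sorted by time in R
  int ev_next = 0;

  // --- background streams ---------------------------------------------------
  const int nbg = bg_syn.size();
  std::vector<SplitMix> bg_rng;
  std::vector<double> bg_next(nbg);
  bg_rng.reserve(nbg);
  for (int b = 0; b < nbg; ++b) {
    bg_rng.emplace_back(
        stream_seed((uint64_t)master_seed, (uint64_t)(100000 + bg_sid[b])));
    bg_next[b] = (bg_rate_ms[b] > 0)
                     ? bg_rng[b].rexp(1.0 / bg_rate_ms[b])
                     : 2.0 * duration;
  }

  // --- recording ------------------------------------------------------------
  const bool do_lfp = lfp_a3.size() > 0;
  const int nrec_t = nsteps / rec_stride + 1;
  std::vector<double> lfp, mean_a3, mean_bd;
  if (do_lfp) {
    lfp.reserve(nrec_t);
    mean_a3.reserve(nrec_t);
    mean_bd.reserve(nrec_t);
  }
  NumericMatrix rec_mat(rec_comps.size() > 0 ? nrec_t : 0, rec_comps.size());
  NumericMatrix fine_mat(fine_comps.size() > 0 ? nsteps + 1 : 0,
                         fine_comps.size());

  std::vector<double> spike_t;
  std::vector<int> spike_cell;
  std::vector<int> last_spike(ncell, -1000000);
  std::vector<char> above(ncell, 0);
  for (int c = 0; c < ncell; ++c) above[c] = V[soma_comp[c]] >= thresh;

  std::vector<double> Gacc(ncomp), Iacc(ncomp);

  double next_ms = 0.0;
  int ms_k = 0;

  auto record = [&](int rrow, int step) {
    if (do_lfp) {
      double sa = 0, sb = 0;
      for (int k = 0; k < lfp_a3.size(); ++k) {
        sa += V[lfp_a3[k]];
        sb += V[lfp_bd[k]];
      }
      sa /= lfp_a3.size();
      sb /= lfp_bd.size();
      lfp.push_back(sa - sb);
      mean_a3.push_back(sa);
      mean_bd.push_back(sb);
    }
    for (int k = 0; k < rec_comps.size(); ++k) rec_mat(rrow, k) = V[rec_comps[k]];
    (void)step;
  };
  if (rec_comps.size() > 0 || do_lfp) record(0, 0);
  for (int k = 0; k < fine_comps.size(); ++k) fine_mat(0, k) = V[fine_comps[k]];

  // ---------------------------------------------------------------------------
  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;

    // deliver queued synaptic events
    auto& slot = queue[step % qlen];
    for (auto& ev : slot) {
      sA[ev.first] += ev.second;
      sB[ev.first] += ev.second;
    }
    slot.clear();

    // scheduled external events in [t, t+dt)
    while (ev_next < ev_t.size() && ev_t[ev_next] < t + dt) {
      sA[ev_syn[ev_next]] += ev_w[ev_next];
      sB[ev_syn[ev_next]] += ev_w[ev_next];
      ++ev_next;
    }

    // background Poisson events
    for (int b = 0; b < nbg; ++b) {
      while (bg_next[b] < t + dt) {
        sA[bg_syn[b]] += bg_w[b];
        sB[bg_syn[b]] += bg_w[b];
        bg_next[b] += bg_rng[b].rexp(1.0 / bg_rate_ms[b]);
      }
    }

    // medial septum pacemaker (t = 0, P, 2P, ...)
    if (ms_syn.size() > 0 && t + dt > next_ms) {
      for (int k = 0; k < ms_syn.size(); ++k) {
        sA[ms_syn[k]] += ms_w[k];
        sB[ms_syn[k]] += ms_w[k];
      }
      ++ms_k;
      next_ms = ms_k * ms_period_ms;
    }

    std::fill(Gacc.begin(), Gacc.end(), 0.0);
    std::fill(Iacc.begin(), Iacc.end(), 0.0);

    // synaptic conductances, then decay
    for (int s = 0; s < nsyn; ++s) {
      double g = sN[s] * (sB[s] - sA[s]);
      if (g < 0) g = 0;
      int c = syn_comp[s];
      // voltage-dependent Mg2+ block (NMDA only, optional)
      if (syn_mg[s]) g /= 1.0 + mg_eta * std::exp(-mg_gamma * V[c]);
      Gacc[c] += g;
      Iacc[c] += g * syn_E[s];
      sA[s] *= d1[s];
      sB[s] *= d2[s];
    }

    // channels: advance gates, accumulate conductances
    for (auto& C : chans) {
      const size_t nk = C.comps.size();
      std::vector<double> prod(nk, 1.0);
      for (auto& G : C.gates) {
        for (size_t k = 0; k < nk; ++k) {
          double u = tab_idx(V[C.comps[k]]);
          int i = (int)u;
          double f = u - i;
          double mi = G.minf[i] * (1 - f) + G.minf[i + 1] * f;
          double ed = G.edt[i] * (1 - f) + G.edt[i + 1] * f;
          double x = G.x[k] + (mi - G.x[k]) * ed;
          if (x < 0) x = 0;
          if (x > 1) x = 1;
          G.x[k] = x;
          double p = x;
          for (int e = 1; e < G.expn; ++e) p *= x;
          prod[k] *= p;
        }
      }
      for (size_t k = 0; k < nk; ++k) {
        int c = C.comps[k];
        double g = C.gbar[k] * prod[k];
        if (C.ca_gated) {
          double cc = ca[(int)ca_of_comp[c]];
          g *= cc / (cc + C.kd);
        }
        Gacc[c] += g;
        Iacc[c] += g * C.erev;
        if (C.ca_source) {
          int k2 = (int)ca_of_comp[c];
          // nA -> mA/cm^2 : I_nA * 1e-6 / area_cm2
          double i_ca = g * (V[c] - C.erev) * 1e-3;  // nA
          double dens = i_ca * 1e-6 / ca_area_cm2[k2];  // mA/cm^2
          // ca_in ~ 1/(2 F depth) in mM cm^2 / (mA ms)
          ca[k2] += dt * (-ca_in * dens - (ca[k2] - ca_rest) / ca_tau);
          if (ca[k2] < ca_rest) ca[k2] = ca_rest;
        }
      }
    }

    // current injections
    for (int k = 0; k < inj_comp.size(); ++k)
      if (t >= inj_t0[k] && t < inj_t1[k]) Iacc[inj_comp[k]] += inj_nA[k] * 1e3;
    // note: Gacc in nS, Iacc accumulates g*E (nS*mV = pA); injections nA->pA

    // voltage update (semi-implicit; axial neighbours explicit)
    std::vector<double> Vnew(ncomp);
    for (int c = 0; c < ncomp; ++c) {
      double G = Gacc[c];
      double I = Iacc[c];
      for (auto& nb : adj[c]) {
        G += nb.second;
        I += nb.second * V[nb.first];
      }
      // cap_nF/dt in nF/ms = µS; conductances in nS -> use pA/mV = nS
      double a = cap_nF[c] / dt * 1e3;  // nS
      Vnew[c] = (a * V[c] + I) / (a + G);
    }
    V.swap(Vnew);

    // spike detection at somata
    const double tnow = (step + 1) * dt;
    for (int c = 0; c < ncell; ++c) {
      double v = V[soma_comp[c]];
      if (v >= thresh) {
        if (!above[c] && (step + 1 - last_spike[c]) > refrac_steps) {
          last_spike[c] = step + 1;
          spike_t.push_back(tnow);
          spike_cell.push_back(c + 1);
          for (int e = edge_ptr[c]; e < edge_ptr[c + 1]; ++e) {
            int arrive = (step + 1 + edge_delay[e]) % qlen;
            queue[arrive].push_back({edge_syn[e], edge_w[e]});
          }
        }
        above[c] = 1;
      } else {
        above[c] = 0;
      }
    }

    // recording
    if ((step + 1) % rec_stride == 0 && (rec_comps.size() > 0 || do_lfp))
      record((step + 1) / rec_stride, step + 1);
    if (fine_comps.size() > 0)
      for (int k = 0; k < fine_comps.size(); ++k)
        fine_mat(step + 1, k) = V[fine_comps[k]];

    // divergence check
    if ((step & 1023) == 0) {
      for (int c = 0; c < ncomp; ++c)
        if (!std::isfinite(V[c])) {
          int cell = -1;
          for (int cc = 0; cc < ncell; ++cc)
            if (soma_comp[cc] <= c) cell = cc + 1;
          stop("integration diverged (non-finite voltage) at t = %.2f ms, "
               "compartment %d (cell %d)", tnow, c + 1, cell);
        }
    }
    if ((step & 8191) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["spike_t"] = wrap(spike_t), _["spike_cell"] = wrap(spike_cell),
      _["lfp"] = wrap(lfp), _["mean_adend3"] = wrap(mean_a3),
      _["mean_bdend"] = wrap(mean_bd), _["rec"] = rec_mat,
      _["fine"] = fine_mat, _["rec_dt"] = rec_stride * dt, _["dt"] = dt);
  return out;
}
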
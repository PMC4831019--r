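// Monodomain 1D cable integrator with a reduced human ventricular membrane
// model. The fast sodium current follows the ten Tusscher-Panfilov human
// ventricular formulation (m^3 h j); repolarisation uses simplified
// currents: an inward rectifier IK1, a delayed-rectifier IKr-like current,
// an L-type Ca-like current and an optional background leak. Gates advance
// by Rush-Larsen steps taken from a precomputed voltage lookup table;
// membrane potential and diffusion advance by forward Euler with no-flux
// boundaries.
//
// Per-node parameter columns:
//   0 gNa  (mS/uF)   1 shift (mV, activation-gate voltage translation)
//   2 gK1  3 gKr  4 gCaL  5 gleak  6 Eleak (mV)
//   7 hshift (mV, optional translation of the inactivation gates)

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double V_LO = -150.0, V_HI = 100.0, V_STEP = 0.05;
const int NV = (int)((V_HI - V_LO) / V_STEP) + 1;

struct GateLut {
  // steady state and Rush-Larsen factor exp(-dt/tau) per voltage bin
  std::vector<double> m_inf, m_rl, hf_inf, hf_rl, hs_inf, hs_rl, j_inf, j_rl,
      xr_inf, xr_rl, d_inf, d_rl, f_inf, f_rl, k1_inf;
};

inline double clampv(double v) {
  if (v < V_LO) return V_LO;
  if (v > V_HI) return V_HI;
  return v;
}

inline int vidx(double v) { return (int)((clampv(v) - V_LO) / V_STEP + 0.5); }

// Fast-INa gate kinetics of the ten Tusscher-Panfilov human ventricular
// model (m^3 h j); chosen over alternatives for its robust conduction at
// slow transmural velocities.
inline double mss(double v) {
  double s = 1.0 + exp((-56.86 - v) / 9.03);
  return 1.0 / (s * s);
}
inline double tm(double v) {
  double am = 1.0 / (1.0 + exp((-60.0 - v) / 5.0));
  double bm = 0.1 / (1.0 + exp((v + 35.0) / 5.0)) +
              0.1 / (1.0 + exp((v - 50.0) / 200.0));
  return am * bm;
}
inline double hss(double v) {
  double s = 1.0 + exp((v + 71.55) / 7.43);
  return 1.0 / (s * s);
}
inline double thf(double v) {
  double ah = (v < -40.0) ? 0.057 * exp(-(v + 80.0) / 6.8) : 0.0;
  double bh = (v < -40.0)
                  ? (2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v))
                  : (0.77 / (0.13 * (1.0 + exp(-(v + 10.66) / 11.1))));
  return 1.0 / (ah + bh);
}
inline double ths(double v) { return thf(v); }  // single h gate (weight below)
inline double tj(double v) {
  double aj = (v < -40.0)
                  ? ((-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
                     (v + 37.78) / (1.0 + exp(0.311 * (v + 79.23))))
                  : 0.0;
  double bj = (v < -40.0)
                  ? (0.02424 * exp(-0.01052 * v) / (1.0 + exp(-0.1378 * (v + 40.14))))
                  : (0.6 * exp(0.057 * v) / (1.0 + exp(-0.1 * (v + 32.0))));
  return 1.0 / (aj + bj);
}
// simplified repolarising kinetics
inline double xrss(double v) { return 1.0 / (1.0 + exp(-(v + 15.0) / 8.0)); }
inline double txr(double v) { return 120.0 + 300.0 * exp(-pow((v + 25.0) / 30.0, 2)); }
inline double dss(double v) { return 1.0 / (1.0 + exp(-(v + 10.0) / 6.24)); }
inline double td(double v) { return 0.6 + 1.2 * exp(-pow((v + 15.0) / 25.0, 2)); }
inline double fss(double v) { return 1.0 / (1.0 + exp((v + 30.0) / 7.0)); }
inline double tf(double v) { return 30.0 + 250.0 * exp(-pow((v + 25.0) / 30.0, 2)); }
inline double k1ss(double v) { return 1.0 / (1.0 + exp((v + 75.0) / 5.0)); }

GateLut build_lut(double dt) {
  GateLut L;
  L.m_inf.resize(NV); L.m_rl.resize(NV); L.hf_inf.resize(NV); L.hf_rl.resize(NV);
  L.hs_inf.resize(NV); L.hs_rl.resize(NV); L.j_inf.resize(NV); L.j_rl.resize(NV);
  L.xr_inf.resize(NV); L.xr_rl.resize(NV); L.d_inf.resize(NV); L.d_rl.resize(NV);
  L.f_inf.resize(NV); L.f_rl.resize(NV); L.k1_inf.resize(NV);
  for (int i = 0; i < NV; ++i) {
    double v = V_LO + i * V_STEP;
    L.m_inf[i] = mss(v);  L.m_rl[i] = exp(-dt / tm(v));
    L.hf_inf[i] = hss(v); L.hf_rl[i] = exp(-dt / thf(v));
    L.hs_inf[i] = hss(v); L.hs_rl[i] = exp(-dt / ths(v));
    L.j_inf[i] = hss(v);  L.j_rl[i] = exp(-dt / tj(v));
    L.xr_inf[i] = xrss(v); L.xr_rl[i] = exp(-dt / txr(v));
    L.d_inf[i] = dss(v);  L.d_rl[i] = exp(-dt / td(v));
    L.f_inf[i] = fss(v);  L.f_rl[i] = exp(-dt / tf(v));
    L.k1_inf[i] = k1ss(v);
  }
  return L;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_cable(NumericMatrix params, double dx, double dt, double total_ms,
                   NumericVector d_edges, IntegerVector stim_nodes,
                   double stim_amp, double stim_dur_ms, double stim_period_ms,
                   double stim_start_ms, double record_start_ms,
                   double record_every_ms, double ena, double ek, double eca,
                   double act_threshold, Nullable<NumericMatrix> state0 = R_NilValue) {
  const int n = params.nrow();
  if (params.ncol() != 8) stop("params must have 8 columns");
  if (n > 1 && d_edges.size() != n - 1) stop("d_edges must have n-1 entries");

  GateLut L = build_lut(dt);

  // state arrays
  std::vector<double> V(n), m(n), hf(n), hs(n), j(n), xr(n), d(n), f(n);
  if (state0.isNotNull()) {
    NumericMatrix s0(state0);
    if (s0.nrow() != n || s0.ncol() != 8) stop("state0 must be n x 8");
    for (int i = 0; i < n; ++i) {
      V[i] = s0(i, 0); m[i] = s0(i, 1); hf[i] = s0(i, 2); hs[i] = s0(i, 3);
      j[i] = s0(i, 4); xr[i] = s0(i, 5); d[i] = s0(i, 6); f[i] = s0(i, 7);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double vr = -88.0; // all nodes start near ventricular rest and settle
      V[i] = vr;
      int k = vidx(vr);
      m[i] = L.m_inf[k]; hf[i] = L.hf_inf[k]; hs[i] = L.hs_inf[k];
      j[i] = L.j_inf[k]; xr[i] = L.xr_inf[k]; d[i] = L.d_inf[k]; f[i] = L.f_inf[k];
    }
  }

  // cache per-node parameters in flat arrays (hot loop)
  std::vector<double> pgNa(n), pshift(n), pgK1(n), pgKr(n), pgCaL(n),
      pgleak(n), peleak(n), phshift(n), pD(n > 1 ? n - 1 : 0);
  for (int i = 0; i < n; ++i) {
    pgNa[i] = params(i, 0); pshift[i] = params(i, 1); pgK1[i] = params(i, 2);
    pgKr[i] = params(i, 3); pgCaL[i] = params(i, 4); pgleak[i] = params(i, 5);
    peleak[i] = params(i, 6); phshift[i] = params(i, 7);
  }
  for (int i = 0; i + 1 < n; ++i) pD[i] = d_edges[i];

  std::vector<char> is_stim(n, 0);
  for (int s = 0; s < stim_nodes.size(); ++s) {
    int k = stim_nodes[s];
    if (k < 0 || k >= n) stop("stimulus node out of range");
    is_stim[k] = 1;
  }

  const long n_steps = (long)std::llround(total_ms / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_every_ms / dt));
  const long rec_start = (long)std::llround(record_start_ms / dt);
  const int n_frames = (int)((n_steps - rec_start) / rec_every) + 1;
  NumericMatrix Vrec(n_frames, n);
  NumericVector trec(n_frames);
  int frame = 0;

  std::vector<double> act_last(n, NA_REAL);
  std::vector<int> act_count(n, 0);
  std::vector<double> dvdt_max(n, 0.0), dvdt_tmax(n, NA_REAL);
  std::vector<double> Vnew(n);

  const bool periodic = stim_period_ms > 0;
  const long stim_start_steps = (long)std::llround(stim_start_ms / dt);
  const long stim_dur_steps = (long)std::llround(stim_dur_ms / dt);
  const long stim_period_steps =
      periodic ? std::max(1L, (long)std::llround(stim_period_ms / dt)) : 0L;

  for (long step = 0; step <= n_steps; ++step) {
    double t = step * dt;

    // record
    if (step >= rec_start && (step - rec_start) % rec_every == 0 && frame < n_frames) {
      for (int i = 0; i < n; ++i) Vrec(frame, i) = V[i];
      trec[frame] = t;
      ++frame;
    }
    if (step == n_steps) break;

    // stimulus window (integer step arithmetic; avoids fmod)
    bool stim_on = false;
    if (step >= stim_start_steps) {
      long ph = step - stim_start_steps;
      if (periodic) ph %= stim_period_steps;
      stim_on = ph < stim_dur_steps;
    }

    for (int i = 0; i < n; ++i) {
      double v = V[i];
      const double gNa = pgNa[i], shift = pshift[i], gK1 = pgK1[i],
                   gKr = pgKr[i], gCaL = pgCaL[i], gleak = pgleak[i],
                   eleak = peleak[i];
      // gates (Rush-Larsen from LUT); activation gate on a shifted axis,
      // inactivation gates optionally on their own shifted axis
      int km = vidx(v - shift);
      int kv = vidx(v);
      int kh = (phshift[i] == 0.0) ? kv : vidx(v - phshift[i]);
      m[i] = L.m_inf[km] + (m[i] - L.m_inf[km]) * L.m_rl[km];
      hf[i] = L.hf_inf[kh] + (hf[i] - L.hf_inf[kh]) * L.hf_rl[kh];
      hs[i] = L.hs_inf[kh] + (hs[i] - L.hs_inf[kh]) * L.hs_rl[kh];
      j[i] = L.j_inf[kh] + (j[i] - L.j_inf[kh]) * L.j_rl[kh];
      xr[i] = L.xr_inf[kv] + (xr[i] - L.xr_inf[kv]) * L.xr_rl[kv];
      d[i] = L.d_inf[kv] + (d[i] - L.d_inf[kv]) * L.d_rl[kv];
      f[i] = L.f_inf[kv] + (f[i] - L.f_inf[kv]) * L.f_rl[kv];

      double h = hf[i];  // single TP06 h gate; the hs slot is unused
      double ina = gNa * m[i] * m[i] * m[i] * h * j[i] * (v - ena);
      double ik1 = gK1 * L.k1_inf[kv] * (v - ek);
      double ikr = gKr * xr[i] * (v - ek);
      double ical = gCaL * d[i] * f[i] * (v - eca);
      double ileak = gleak * (v - eleak);
      double iion = ina + ik1 + ikr + ical + ileak;

      double idiff = 0.0;
      if (n > 1) {
        if (i > 0) idiff += pD[i - 1] * (V[i - 1] - v);
        if (i < n - 1) idiff += pD[i] * (V[i + 1] - v);
        idiff /= (dx * dx);
      }
      double istim = (stim_on && is_stim[i]) ? stim_amp : 0.0;
      double dv = dt * (-iion + idiff + istim);
      Vnew[i] = v + dv;

      if (t >= record_start_ms) {
        double rate = dv / dt;
        if (rate > dvdt_max[i]) { dvdt_max[i] = rate; dvdt_tmax[i] = t; }
      }
      if (v < act_threshold && Vnew[i] >= act_threshold) {
        // sub-step linear interpolation of the crossing time
        act_last[i] = t + dt * (act_threshold - v) / (Vnew[i] - v);
        ++act_count[i];
      }
      if (!std::isfinite(Vnew[i]))
        stop("numerical blow-up (non-finite V) at node %d, t = %f ms", i + 1, t);
    }
    std::swap(V, Vnew);
  }

  NumericMatrix fin(n, 8);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = V[i]; fin(i, 1) = m[i]; fin(i, 2) = hf[i]; fin(i, 3) = hs[i];
    fin(i, 4) = j[i]; fin(i, 5) = xr[i]; fin(i, 6) = d[i]; fin(i, 7) = f[i];
  }
  return List::create(
      _["v"] = Vrec, _["time"] = trec,
      _["activation_last"] = NumericVector(act_last.begin(), act_last.end()),
      _["n_activations"] = IntegerVector(act_count.begin(), act_count.end()),
      _["dvdt_max"] = NumericVector(dvdt_max.begin(), dvdt_max.end()),
      _["dvdt_tmax"] = NumericVector(dvdt_tmax.begin(), dvdt_tmax.end()),
      _["final_state"] = fin);
}
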
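#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit monodomain stepping on packed active-node arrays, optionally with a
// second domain and two-phase resistive coupling at listed node pairs.
//
// Per domain:
//   v, h        state vectors (length n)
//   nb          n x ndirs neighbor index matrix (0-based into packed arrays,
//               -1 = no active neighbor / no-flux face)
//   g           n x ndirs face conductances, g = phi_face * D_face / h_axis^2
//   inv_phi     1 / phi_i for the phase-field divergence form
//   pars        c(tau_in, tau_out, tau_open, tau_close, v_gate)
//   stim_node / stim_amp / stim_start / stim_dur  independent stimulus entries
//   act         first-crossing times (NA until activated), updated in place on
//               a copy; crossing of v_thresh detected on the full step update
//               with linear sub-dt interpolation.
//
// Two-phase coupling (second phase after all grid points are updated):
//   va[pa] += dt * g_c * (vb[pb] - va[pa]);  vb[pb] += dt * g_c * (va[pa] - vb[pb])
// computed from the phase-1 (post-update) values, so the pairwise sum is
// conserved by the exchange.

struct Domain {
  NumericVector v, h, inv_phi, act;
  IntegerMatrix nb;
  NumericMatrix g;
  double tau_in, tau_out, tau_open, tau_close, v_gate;
  IntegerVector stim_node;
  NumericVector stim_amp, stim_start, stim_dur;
  std::vector<double> v_new;
  int n;
};

static Domain unpack(List d) {
  Domain out;
  out.v = clone(as<NumericVector>(d["v"]));
  out.h = clone(as<NumericVector>(d["h"]));
  out.inv_phi = as<NumericVector>(d["inv_phi"]);
  out.act = clone(as<NumericVector>(d["act"]));
  out.nb = as<IntegerMatrix>(d["nb"]);
  out.g = as<NumericMatrix>(d["g"]);
  NumericVector p = as<NumericVector>(d["pars"]);
  out.tau_in = p[0]; out.tau_out = p[1]; out.tau_open = p[2];
  out.tau_close = p[3]; out.v_gate = p[4];
  out.stim_node = as<IntegerVector>(d["stim_node"]);
  out.stim_amp = as<NumericVector>(d["stim_amp"]);
  out.stim_start = as<NumericVector>(d["stim_start"]);
  out.stim_dur = as<NumericVector>(d["stim_dur"]);
  out.n = out.v.size();
  out.v_new.resize(out.n);
  return out;
}

static inline void step_domain(Domain &d, double t, double dt, bool react) {
  const int n = d.n, nd = d.nb.ncol();
  const double ea_open = std::exp(-dt / d.tau_open);
  const double ea_close = std::exp(-dt / d.tau_close);
  for (int i = 0; i < n; ++i) {
    double vi = d.v[i];
    double diff = 0.0;
    for (int k = 0; k < nd; ++k) {
      int j = d.nb(i, k);
      if (j >= 0) diff += d.g(i, k) * (d.v[j] - vi);
    }
    diff *= d.inv_phi[i];
    double dv = diff;
    if (react) {
      double hi = d.h[i];
      dv += hi * vi * vi * (1.0 - vi) / d.tau_in - vi / d.tau_out;
      // exact exponential gate update of the piecewise-linear gate ODE
      d.h[i] = (vi < d.v_gate) ? 1.0 + (hi - 1.0) * ea_open : hi * ea_close;
    }
    d.v_new[i] = vi + dt * dv;
  }
  // stimulus currents (constant over [start, start + dur))
  for (int s = 0; s < d.stim_node.size(); ++s) {
    if (t >= d.stim_start[s] && t < d.stim_start[s] + d.stim_dur[s])
      d.v_new[d.stim_node[s]] += dt * d.stim_amp[s];
  }
}

static inline void record_activation(Domain &d, const std::vector<double> &v_prev,
                                     double t, double dt, double thr) {
  for (int i = 0; i < d.n; ++i) {
    if (!NumericVector::is_na(d.act[i])) continue;
    double v0 = v_prev[i], v1 = d.v[i];
    if (v0 < thr && v1 >= thr)
      d.act[i] = t + dt * (thr - v0) / (v1 - v0);
  }
}

static int n_unactivated(const Domain &d) {
  int c = 0;
  for (int i = 0; i < d.n; ++i) if (NumericVector::is_na(d.act[i])) ++c;
  return c;
}

// [[Rcpp::export]]
List cpp_run(List domA, List domB, IntegerVector pair_a, IntegerVector pair_b,
             double g_c, double dt, double t0, int n_steps, double v_thresh,
             bool react, bool stop_when_activated, int snapshot_every) {
  Domain A = unpack(domA);
  bool haveB = as<int>(domB["n"]) > 0;
  Domain B;
  if (haveB) B = unpack(domB);
  std::vector<double> prevA(A.n), prevB(haveB ? B.n : 0);
  List snapsA, snapsB;
  double t = t0;
  int done = 0;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < A.n; ++i) prevA[i] = A.v[i];
    if (haveB) for (int i = 0; i < B.n; ++i) prevB[i] = B.v[i];
    step_domain(A, t, dt, react);
    if (haveB) step_domain(B, t, dt, react);
    for (int i = 0; i < A.n; ++i) A.v[i] = A.v_new[i];
    if (haveB) for (int i = 0; i < B.n; ++i) B.v[i] = B.v_new[i];
    // phase 2: two-way coupling from phase-1 values
    if (haveB && pair_a.size() > 0 && g_c != 0.0) {
      for (int p = 0; p < pair_a.size(); ++p) {
        int ia = pair_a[p], ib = pair_b[p];
        double va = A.v[ia], vb = B.v[ib];
        A.v[ia] = va + dt * g_c * (vb - va);
        B.v[ib] = vb + dt * g_c * (va - vb);
      }
    }
    record_activation(A, prevA, t, dt, v_thresh);
    if (haveB) record_activation(B, prevB, t, dt, v_thresh);
    t += dt;
    ++done;
    if (step % 200 == 0) {
      for (int i = 0; i < A.n; ++i)
        if (!std::isfinite(A.v[i]))
          stop("NaN/Inf detected in membrane variable at t = %f ms", t);
      if (haveB)
        for (int i = 0; i < B.n; ++i)
          if (!std::isfinite(B.v[i]))
            stop("NaN/Inf detected in membrane variable at t = %f ms", t);
    }
    if (snapshot_every > 0 && (step + 1) % snapshot_every == 0) {
      snapsA.push_back(clone(A.v));
      if (haveB) snapsB.push_back(clone(B.v));
    }
    if (stop_when_activated && n_unactivated(A) == 0 &&
        (!haveB || n_unactivated(B) == 0)) break;
  }
  List out = List::create(
    _["vA"] = A.v, _["hA"] = A.h, _["actA"] = A.act,
    _["time"] = t, _["steps"] = done,
    _["snapsA"] = snapsA);
  if (haveB) {
    out["vB"] = B.v; out["hB"] = B.h; out["actB"] = B.act;
    out["snapsB"] = snapsB;
  }
  return out;
}
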
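// Monodomain reaction-diffusion solvers: 0D (single cell), 1D cable with a
// per-node diffusion profile (heterogeneous interfaces via harmonic-mean
// face values, no-flux boundaries), and 2D sheet with uniform diffusion.
// dV/dt = div(D grad V) - I_ion + I_stim, currents in pA/pF (== mV/ms).

#include "models.h"
#include <Rcpp.h>
using namespace Rcpp;

struct StimEp {
  double onset, dur, amp;
  int lo, hi;  // node range, inclusive
};

static std::vector<StimEp> parse_stim(const NumericMatrix& stim) {
  std::vector<StimEp> eps;
  for (int r = 0; r < stim.nrow(); ++r) {
    StimEp e;
    e.onset = stim(r, 0); e.dur = stim(r, 1); e.amp = stim(r, 2);
    e.lo = (int)stim(r, 3); e.hi = (int)stim(r, 4);
    eps.push_back(e);
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_sim_cable(int model_id, List param_sets, IntegerVector node_set,
                   Nullable<NumericMatrix> init_state,
                   NumericVector d_profile, double dx, double dt,
                   double duration, NumericMatrix stim, double record_dt,
                   IntegerVector record_nodes, NumericVector snapshot_times) {
  const CellModel& mdl = get_model(model_id);
  const int ns = mdl.n_state;
  const int nn = node_set.size();
  const int nsets = param_sets.size();

  std::vector<std::vector<double>> pars(nsets);
  std::vector<Lut> luts(nsets);
  for (int s = 0; s < nsets; ++s) {
    NumericVector p = param_sets[s];
    pars[s].assign(p.begin(), p.end());
    mdl.build_lut(luts[s], pars[s].data(), dt);
  }

  std::vector<double> y((size_t)ns * nn);
  if (init_state.isNotNull()) {
    NumericMatrix is(init_state);
    if (is.nrow() != ns || is.ncol() != nn)
      stop("init_state has wrong dimensions");
    for (int i = 0; i < nn; ++i)
      for (int k = 0; k < ns; ++k) y[(size_t)i * ns + k] = is(k, i);
  } else {
    for (int i = 0; i < nn; ++i) mdl.default_state(&y[(size_t)i * ns]);
  }

  // harmonic-mean face diffusion coefficients / dx^2
  std::vector<double> face(nn > 1 ? nn - 1 : 0);
  for (int i = 0; i + 1 < nn; ++i) {
    double a = d_profile[i], b = d_profile[i + 1];
    face[i] = (a > 0 && b > 0) ? 2.0 * a * b / (a + b) / (dx * dx) : 0.0;
  }

  std::vector<StimEp> eps = parse_stim(stim);

  const long n_steps = (long)std::llround(duration / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  const long n_rec = n_steps / rec_every + 1;
  IntegerVector rnodes = record_nodes.size() ? record_nodes
                                             : seq_len(nn) - 1;
  const int nr = rnodes.size();
  NumericMatrix vrec(n_rec, nr);
  NumericVector trec(n_rec);
  List snapshots(snapshot_times.size());
  std::vector<long> snap_step(snapshot_times.size());
  for (int q = 0; q < snapshot_times.size(); ++q)
    snap_step[q] = (long)std::llround(snapshot_times[q] / dt);

  std::vector<double> vnow(nn), lap(nn, 0.0);
  long ri = 0;
  const long check_every = std::max(1L, (long)std::llround(1.0 / dt));

  for (long s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    if (s % rec_every == 0 && ri < n_rec) {
      trec[ri] = t;
      for (int c = 0; c < nr; ++c) vrec(ri, c) = y[(size_t)rnodes[c] * ns];
      ++ri;
    }
    for (int q = 0; q < (int)snap_step.size(); ++q) {
      if (s == snap_step[q]) {
        NumericMatrix sn(ns, nn);
        for (int i = 0; i < nn; ++i)
          for (int k = 0; k < ns; ++k) sn(k, i) = y[(size_t)i * ns + k];
        snapshots[q] = sn;
      }
    }
    if (s == n_steps) break;

    for (int i = 0; i < nn; ++i) vnow[i] = y[(size_t)i * ns];
    if (nn > 1) {
      for (int i = 0; i < nn; ++i) {
        double acc = 0.0;
        if (i > 0) acc += face[i - 1] * (vnow[i - 1] - vnow[i]);
        if (i + 1 < nn) acc += face[i] * (vnow[i + 1] - vnow[i]);
        lap[i] = acc;
      }
    }

    for (int i = 0; i < nn; ++i) {
      double iext = lap[i];
      for (const StimEp& e : eps)
        if (t >= e.onset && t < e.onset + e.dur && i >= e.lo && i <= e.hi)
          iext += e.amp;
      int si = node_set[i];
      mdl.step(&y[(size_t)i * ns], pars[si].data(), luts[si], dt, iext);
    }

    if (s % check_every == 0) {
      for (int i = 0; i < nn; ++i) {
        double v = y[(size_t)i * ns];
        if (!std::isfinite(v) || std::fabs(v) > 250.0)
          stop("numerical blow-up at node %d, t = %.2f ms", i + 1, t);
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fin(ns, nn);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < ns; ++k) fin(k, i) = y[(size_t)i * ns + k];

  return List::create(_["time"] = trec, _["v"] = vrec,
                      _["record_nodes"] = rnodes + 1,
                      _["final_state"] = fin, _["snapshots"] = snapshots);
}

// [[Rcpp::export]]
List cpp_sim_sheet(int model_id, NumericVector params, int nx, int ny,
                   Nullable<NumericMatrix> init_state, double D, double dx,
                   double dt, double duration, NumericMatrix stim_rect,
                   IntegerVector record_sites, double record_dt,
                   NumericVector field_times) {
  const CellModel& mdl = get_model(model_id);
  const int ns = mdl.n_state;
  const int nn = nx * ny;

  std::vector<double> par(params.begin(), params.end());
  Lut lut;
  mdl.build_lut(lut, par.data(), dt);

  std::vector<double> y((size_t)ns * nn);
  if (init_state.isNotNull()) {
    NumericMatrix is(init_state);
    if (is.nrow() != ns || is.ncol() != nn)
      stop("init_state has wrong dimensions");
    for (int i = 0; i < nn; ++i)
      for (int k = 0; k < ns; ++k) y[(size_t)i * ns + k] = is(k, i);
  } else {
    for (int i = 0; i < nn; ++i) mdl.default_state(&y[(size_t)i * ns]);
  }

  // stim_rect rows: onset, duration, amplitude, x0, x1, y0, y1 (0-based)
  struct RectEp { double onset, dur, amp; int x0, x1, y0, y1; };
  std::vector<RectEp> eps;
  for (int r = 0; r < stim_rect.nrow(); ++r)
    eps.push_back({stim_rect(r, 0), stim_rect(r, 1), stim_rect(r, 2),
                   (int)stim_rect(r, 3), (int)stim_rect(r, 4),
                   (int)stim_rect(r, 5), (int)stim_rect(r, 6)});

  const double dcoef = D / (dx * dx);
  const long n_steps = (long)std::llround(duration / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  const long n_rec = n_steps / rec_every + 1;
  const int nsite = record_sites.size();
  NumericMatrix site_v(n_rec, nsite);
  NumericVector trec(n_rec), vmax_rec(n_rec);
  List fields(field_times.size());
  std::vector<long> field_step(field_times.size());
  for (int q = 0; q < field_times.size(); ++q)
    field_step[q] = (long)std::llround(field_times[q] / dt);

  std::vector<double> vnow(nn), lap(nn);
  long ri = 0;
  const long check_every = std::max(1L, (long)std::llround(1.0 / dt));

  for (long s = 0; s <= n_steps; ++s) {
    double t = s * dt;
    if (s % rec_every == 0 && ri < n_rec) {
      trec[ri] = t;
      double vmax = -1e9;
      for (int i = 0; i < nn; ++i) {
        double v = y[(size_t)i * ns];
        if (v > vmax) vmax = v;
      }
      vmax_rec[ri] = vmax;
      for (int c = 0; c < nsite; ++c)
        site_v(ri, c) = y[(size_t)record_sites[c] * ns];
      ++ri;
    }
    for (int q = 0; q < (int)field_step.size(); ++q) {
      if (s == field_step[q]) {
        NumericVector f(nn);
        for (int i = 0; i < nn; ++i) f[i] = y[(size_t)i * ns];
        fields[q] = f;
      }
    }
    if (s == n_steps) break;

    for (int i = 0; i < nn; ++i) vnow[i] = y[(size_t)i * ns];
    // 5-point Laplacian with mirrored (no-flux) boundaries
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int i = iy * nx + ix;
        double c = vnow[i], acc = 0.0;
        acc += (ix > 0 ? vnow[i - 1] : c) - c;
        acc += (ix + 1 < nx ? vnow[i + 1] : c) - c;
        acc += (iy > 0 ? vnow[i - nx] : c) - c;
        acc += (iy + 1 < ny ? vnow[i + nx] : c) - c;
        lap[i] = dcoef * acc;
      }
    }

    bool any_stim = false;
    for (const RectEp& e : eps)
      if (t >= e.onset && t < e.onset + e.dur) { any_stim = true; break; }

    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int i = iy * nx + ix;
        double iext = lap[i];
        if (any_stim)
          for (const RectEp& e : eps)
            if (t >= e.onset && t < e.onset + e.dur && ix >= e.x0 &&
                ix <= e.x1 && iy >= e.y0 && iy <= e.y1)
              iext += e.amp;
        mdl.step(&y[(size_t)i * ns], par.data(), lut, dt, iext);
      }
    }

    if (s % check_every == 0) {
      for (int i = 0; i < nn; ++i) {
        double v = y[(size_t)i * ns];
        if (!std::isfinite(v) || std::fabs(v) > 250.0)
          stop("numerical blow-up at node %d, t = %.2f ms", i + 1, t);
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fin(ns, nn);
  for (int i = 0; i < nn; ++i)
    for (int k = 0; k < ns; ++k) fin(k, i) = y[(size_t)i * ns + k];

  return List::create(_["time"] = trec, _["site_v"] = site_v,
                      _["vmax"] = vmax_rec, _["final_state"] = fin,
                      _["fields"] = fields);
}

// [[Rcpp::export]]
int cpp_model_n_state(int model_id) { return get_model(model_id).n_state; }

// [[Rcpp::export]]
NumericVector cpp_model_default_state(int model_id) {
  const CellModel& mdl = get_model(model_id);
  NumericVector y(mdl.n_state);
  mdl.default_state(y.begin());
  return y;
}
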
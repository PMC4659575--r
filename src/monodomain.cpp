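// Deformation-aware monodomain solver on regular 1D/2D lattices.
// dV/dt = -(I_ion + I_stim) + div( D C^-1 grad V )
// Strang splitting: half reaction / full Crank-Nicolson diffusion / half
// reaction. The diffusion solve is matrix-free BiCGStab with Jacobi
// preconditioning (the 9-point operator is symmetric up to the cross-term
// boundary closure).
#include <Rcpp.h>
#include "cellmodel.h"
using namespace Rcpp;
using namespace atriamech;

namespace {

struct Lattice {
  int nx, ny;
  double dx;
  // effective tensor per node (already D * C^-1), mm^2/ms
  std::vector<double> Mxx, Mxy, Myy;
  int n() const { return nx * ny; }
  int id(int ix, int iy) const { return iy * nx + ix; }
};

// y-derivative (central, one-sided at boundaries) of v at node
inline double dvdy(const Lattice& g, const std::vector<double>& v,
                   int ix, int iy) {
  if (g.ny == 1) return 0.0;
  const int i = g.id(ix, iy);
  if (iy == 0) return (v[i + g.nx] - v[i]) / g.dx;
  if (iy == g.ny - 1) return (v[i] - v[i - g.nx]) / g.dx;
  return (v[i + g.nx] - v[i - g.nx]) / (2.0 * g.dx);
}

inline double dvdx(const Lattice& g, const std::vector<double>& v,
                   int ix, int iy) {
  const int i = g.id(ix, iy);
  if (ix == 0) return (v[i + 1] - v[i]) / g.dx;
  if (ix == g.nx - 1) return (v[i] - v[i - 1]) / g.dx;
  return (v[i + 1] - v[i - 1]) / (2.0 * g.dx);
}

// L v = div(M grad v) with zero-flux faces on the boundary
void apply_L(const Lattice& g, const std::vector<double>& v,
             std::vector<double>& out) {
  const double dx = g.dx;
  for (int iy = 0; iy < g.ny; ++iy) {
    for (int ix = 0; ix < g.nx; ++ix) {
      const int i = g.id(ix, iy);
      double div = 0.0;
      // x faces
      if (ix + 1 < g.nx) {
        const int j = i + 1;
        const double mxx = 0.5 * (g.Mxx[i] + g.Mxx[j]);
        const double mxy = 0.5 * (g.Mxy[i] + g.Mxy[j]);
        double flux = mxx * (v[j] - v[i]) / dx;
        if (g.ny > 1 && mxy != 0.0)
          flux += mxy * 0.5 * (dvdy(g, v, ix, iy) + dvdy(g, v, ix + 1, iy));
        div += flux / dx;
      }
      if (ix > 0) {
        const int j = i - 1;
        const double mxx = 0.5 * (g.Mxx[i] + g.Mxx[j]);
        const double mxy = 0.5 * (g.Mxy[i] + g.Mxy[j]);
        double flux = mxx * (v[i] - v[j]) / dx;
        if (g.ny > 1 && mxy != 0.0)
          flux += mxy * 0.5 * (dvdy(g, v, ix, iy) + dvdy(g, v, ix - 1, iy));
        div -= flux / dx;
      }
      // y faces
      if (g.ny > 1) {
        if (iy + 1 < g.ny) {
          const int j = i + g.nx;
          const double myy = 0.5 * (g.Myy[i] + g.Myy[j]);
          const double mxy = 0.5 * (g.Mxy[i] + g.Mxy[j]);
          double flux = myy * (v[j] - v[i]) / dx;
          if (mxy != 0.0)
            flux += mxy * 0.5 * (dvdx(g, v, ix, iy) + dvdx(g, v, ix, iy + 1));
          div += flux / dx;
        }
        if (iy > 0) {
          const int j = i - g.nx;
          const double myy = 0.5 * (g.Myy[i] + g.Myy[j]);
          const double mxy = 0.5 * (g.Mxy[i] + g.Mxy[j]);
          double flux = myy * (v[i] - v[j]) / dx;
          if (mxy != 0.0)
            flux += mxy * 0.5 * (dvdx(g, v, ix, iy) + dvdx(g, v, ix, iy - 1));
          div -= flux / dx;
        }
      }
      out[i] = div;
    }
  }
}

// Solve (I - a L) x = b by BiCGStab, warm-started from x.
void solve_cn(const Lattice& g, double a, const std::vector<double>& b,
              std::vector<double>& x, double tol, int maxit) {
  const int n = g.n();
  std::vector<double> r(n), r0(n), p(n), vv(n), s(n), t(n), tmp(n);
  apply_L(g, x, tmp);
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b[i] - (x[i] - a * tmp[i]);
    r0[i] = r[i];
    bnorm += b[i] * b[i];
  }
  bnorm = std::sqrt(bnorm) + 1e-300;
  double rho = 1, alpha = 1, omega = 1;
  std::fill(p.begin(), p.end(), 0.0);
  std::fill(vv.begin(), vv.end(), 0.0);
  for (int it = 0; it < maxit; ++it) {
    double rho1 = 0.0;
    for (int i = 0; i < n; ++i) rho1 += r0[i] * r[i];
    if (std::fabs(rho1) < 1e-300) break;
    const double beta = (rho1 / rho) * (alpha / omega);
    rho = rho1;
    for (int i = 0; i < n; ++i) p[i] = r[i] + beta * (p[i] - omega * vv[i]);
    apply_L(g, p, tmp);
    for (int i = 0; i < n; ++i) vv[i] = p[i] - a * tmp[i];
    double r0v = 0.0;
    for (int i = 0; i < n; ++i) r0v += r0[i] * vv[i];
    alpha = rho / r0v;
    double snorm = 0.0;
    for (int i = 0; i < n; ++i) { s[i] = r[i] - alpha * vv[i];
                                  snorm += s[i] * s[i]; }
    if (std::sqrt(snorm) / bnorm < tol) {
      for (int i = 0; i < n; ++i) x[i] += alpha * p[i];
      return;
    }
    apply_L(g, s, tmp);
    double ts = 0.0, tt = 0.0;
    for (int i = 0; i < n; ++i) { t[i] = s[i] - a * tmp[i];
                                  ts += t[i] * s[i]; tt += t[i] * t[i]; }
    omega = ts / (tt + 1e-300);
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i] + omega * s[i];
      r[i] = s[i] - omega * t[i];
      rnorm += r[i] * r[i];
    }
    if (std::sqrt(rnorm) / bnorm < tol) return;
  }
}

} // namespace

// Run the tissue model for t_end ms starting at global time t0.
// states: n x NSTATE matrix (row-major node states), modified copy returned.
// params: NPAR x nsets matrix; set_idx: length-n 0-based index into sets.
// Mxx/Mxy/Myy: effective tensor (D C^-1) per node.
// stim_nodes: list of 0-based node index vectors; stim_t/stim_dur/stim_amp:
// per-event onset (global time), duration, amplitude (pA/pF depolarising).
// probe_nodes: 0-based nodes whose V is recorded every record_dt.
// Returns final states, probe traces, activation bookkeeping (upward
// crossings of -40 mV), time of maximum upstroke rate per node, and the
// time of last activation anywhere.
// [[Rcpp::export]]
List cpp_tissue_run(NumericMatrix states, NumericMatrix params,
                    IntegerVector set_idx, NumericVector Mxx,
                    NumericVector Mxy, NumericVector Myy,
                    int nx, int ny, double dx, double dt, double t0,
                    double t_end, List stim_nodes, NumericVector stim_t,
                    NumericVector stim_dur, NumericVector stim_amp,
                    IntegerVector probe_nodes, double record_dt,
                    int mech_mode = 0, double ode_dt = 0.01,
                    double cg_tol = 1e-8) {
  const int n = nx * ny;
  if (states.nrow() != n || states.ncol() != NSTATE)
    stop("states must be (nx*ny) x %d", NSTATE);
  if (dt <= 0) stop("dt must be positive");
  Lattice g;
  g.nx = nx; g.ny = ny; g.dx = dx;
  g.Mxx.assign(Mxx.begin(), Mxx.end());
  g.Mxy.assign(Mxy.begin(), Mxy.end());
  g.Myy.assign(Myy.begin(), Myy.end());
  if ((int)g.Mxx.size() != n) stop("tensor fields must have nx*ny entries");
  // SPD check of the effective tensor
  for (int i = 0; i < n; ++i) {
    const double det = g.Mxx[i] * g.Myy[i] - g.Mxy[i] * g.Mxy[i];
    if (g.Mxx[i] <= 0 || (ny > 1 && (det <= 0 || g.Myy[i] <= 0)))
      stop("effective diffusion tensor is not positive-definite at node %d",
           i + 1);
  }

  const int nsets = params.ncol();
  std::vector<Par> pars(nsets);
  for (int s = 0; s < nsets; ++s) {
    if (params.nrow() != NPAR) stop("params must be %d x nsets", NPAR);
    par_from_vec(&params(0, s), pars[s]);
    par_prepare(pars[s]);
  }
  for (int i = 0; i < n; ++i)
    if (set_idx[i] < 0 || set_idx[i] >= nsets) stop("set_idx out of range");

  // local state copy, row-major per node
  std::vector<double> S((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) S[(size_t)i * NSTATE + k] = states(i, k);
  std::vector<double> sl_set(n);
  for (int i = 0; i < n; ++i)
    sl_set[i] = pars[set_idx[i]].SL0;

  // stimulus bookkeeping: per-node amplitude at current time
  const int nev = stim_t.size();
  std::vector<std::vector<int>> ev_nodes(nev);
  for (int e = 0; e < nev; ++e) {
    IntegerVector idx = stim_nodes[e];
    ev_nodes[e].assign(idx.begin(), idx.end());
    for (int i : ev_nodes[e])
      if (i < 0 || i >= n) stop("stimulus node index out of range");
  }

  const long nstep = (long)std::ceil(t_end / dt - 1e-9);
  const int nprobe = probe_nodes.size();
  const long rec_every = record_dt > 0
    ? std::max(1L, (long)std::llround(record_dt / dt)) : 0;
  std::vector<double> probe_rec;
  std::vector<double> v(n), rhs(n), tmp(n), istim(n, 0.0);
  std::vector<int> act_count(n, 0);
  std::vector<double> first_act(n, NA_REAL), last_act(n, NA_REAL);
  std::vector<double> max_dvdt(n, -1e300), t_max_dvdt(n, NA_REAL);
  std::vector<double> vprev(n);
  double t_last_any = NA_REAL;
  double cur[NCUR];

  const int nsub = std::max(1, (int)std::lround(std::ceil(dt / 2.0 /
                                                          ode_dt - 1e-9)));
  const double dts = dt / 2.0 / nsub;

  for (long it = 0; it < nstep; ++it) {
    const double t = t0 + it * dt;
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    // current stimulus field
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int e = 0; e < nev; ++e)
      if (t >= stim_t[e] - 1e-9 && t < stim_t[e] + stim_dur[e])
        for (int i : ev_nodes[e]) istim[i] = -stim_amp[e];
    // record probes
    if (rec_every > 0 && it % rec_every == 0) {
      probe_rec.push_back(t);
      for (int q = 0; q < nprobe; ++q)
        probe_rec.push_back(S[(size_t)probe_nodes[q] * NSTATE + iV]);
    }
    for (int i = 0; i < n; ++i) vprev[i] = S[(size_t)i * NSTATE + iV];
    // half reaction
    for (int i = 0; i < n; ++i) {
      double* s = &S[(size_t)i * NSTATE];
      const Par& p = pars[set_idx[i]];
      for (int ss = 0; ss < nsub; ++ss)
        cell_step(p, s, dts, istim[i], mech_mode, sl_set[i], true, cur);
    }
    // full diffusion (Crank-Nicolson)
    for (int i = 0; i < n; ++i) v[i] = S[(size_t)i * NSTATE + iV];
    apply_L(g, v, tmp);
    const double a = dt / 2.0;
    for (int i = 0; i < n; ++i) rhs[i] = v[i] + a * tmp[i];
    solve_cn(g, a, rhs, v, cg_tol, 200);
    for (int i = 0; i < n; ++i) S[(size_t)i * NSTATE + iV] = v[i];
    // half reaction
    for (int i = 0; i < n; ++i) {
      double* s = &S[(size_t)i * NSTATE];
      const Par& p = pars[set_idx[i]];
      for (int ss = 0; ss < nsub; ++ss)
        cell_step(p, s, dts, istim[i], mech_mode, sl_set[i], true, cur);
    }
    // activation bookkeeping
    for (int i = 0; i < n; ++i) {
      const double vn = S[(size_t)i * NSTATE + iV];
      if (!std::isfinite(vn))
        stop("membrane potential non-finite at node %d, t = %.2f", i + 1, t);
      const double dv = (vn - vprev[i]) / dt;
      if (dv > max_dvdt[i]) { max_dvdt[i] = dv; t_max_dvdt[i] = t; }
      if (vprev[i] < -40.0 && vn >= -40.0) {
        act_count[i] += 1;
        if (!R_finite(first_act[i])) first_act[i] = t;
        last_act[i] = t;
        t_last_any = t;
      }
    }
  }

  NumericMatrix out_states(n, NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) out_states(i, k) = S[(size_t)i * NSTATE + k];
  NumericMatrix ptr(nprobe > 0 && rec_every > 0
                      ? (long)probe_rec.size() / (nprobe + 1) : 0,
                    nprobe + 1);
  if (ptr.nrow() > 0)
    for (long r = 0; r < ptr.nrow(); ++r)
      for (int c = 0; c <= nprobe; ++c)
        ptr(r, c) = probe_rec[r * (nprobe + 1) + c];
  return List::create(
    _["states"] = out_states,
    _["probe_trace"] = ptr,
    _["act_count"] = IntegerVector(act_count.begin(), act_count.end()),
    _["first_act"] = NumericVector(first_act.begin(), first_act.end()),
    _["last_act"] = NumericVector(last_act.begin(), last_act.end()),
    _["t_max_dvdt"] = NumericVector(t_max_dvdt.begin(), t_max_dvdt.end()),
    _["max_dvdt"] = NumericVector(max_dvdt.begin(), max_dvdt.end()),
    _["t_last_activation"] = t_last_any);
}
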
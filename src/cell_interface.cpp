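#include <Rcpp.h>
#include "cellmodel.h"
using namespace Rcpp;
using namespace atriamech;

static const char* PARAM_NAMES[NPAR] = {
  "Cm", "F", "R", "T", "V_i", "V_up", "V_rel", "Na_o", "K_o", "Ca_o",
  "g_Na", "g_K1", "g_to", "g_Kr", "g_Ks", "g_CaL", "g_Kur_sc",
  "g_bNa", "g_bCa",
  "i_NaK_max", "Km_Na_i", "Km_K_o",
  "i_NaCa_max", "K_mNa", "K_mCa", "k_sat", "gamma_ncx",
  "i_pCa_max", "Km_pCa",
  "k_rel", "i_up_max", "K_up", "k_leak", "Ca_up_max",
  "CMDN_max", "Km_CMDN", "CSQN_max", "Km_CSQN",
  "tau_tr", "tau_f_Ca", "tau_u", "K_Q10",
  "kon", "koffL", "koffH", "TrpnTot", "perm50", "nperm", "kn_p", "kp_n",
  "fapp", "gapp", "gslmod", "hf", "hfmdc", "hb", "hbmdc", "gxb",
  "sigmap", "sigman", "xPsi", "x_0", "xbmodsp", "TmpC",
  "Qkon", "Qkoff", "Qkn_p", "Qkp_n", "Qfapp", "Qgapp", "Qhf", "Qhb", "Qgxb",
  "SLmin", "SLmax", "len_thick", "len_hbare", "len_thin", "SL0",
  "PCon_t", "PExp_t", "SL_c", "PCon_c", "PExp_c", "visc", "mass",
  "KSE"
};

static const char* STATE_NAMES[NSTATE] = {
  "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fca",
  "u", "v", "w", "Na_i", "K_i", "Ca_i", "Ca_up", "Ca_rel",
  "NNoXB", "PNoXB", "N", "XBprer", "XBpostr", "SL", "xXBprer", "xXBpostr",
  "TRPNCaL", "TRPNCaH", "intf"
};

static const char* CUR_NAMES[NCUR] = {
  "I_Na", "I_K1", "I_to", "I_Kur", "I_Kr", "I_Ks", "I_CaL", "I_pCa",
  "I_NaCa", "I_bNa", "I_bCa", "I_NaK", "I_rel", "I_tr", "I_up", "I_leak",
  "I_ion", "F_active", "dTropTot"
};

static Par make_par(const NumericVector& pv) {
  if (pv.size() != NPAR) stop("parameter vector must have %d entries", NPAR);
  for (int i = 0; i < NPAR; ++i)
    if (!R_finite(pv[i])) stop("non-finite parameter value");
  Par p;
  par_from_vec(REAL(pv), p);
  par_prepare(p);
  return p;
}

static void check_state(const NumericVector& s) {
  if (s.size() != NSTATE) stop("state vector must have %d entries", NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(s[i])) stop("non-finite state value");
}

// [[Rcpp::export]]
CharacterVector cpp_param_names() {
  return CharacterVector(PARAM_NAMES, PARAM_NAMES + NPAR);
}

// [[Rcpp::export]]
CharacterVector cpp_state_names() {
  return CharacterVector(STATE_NAMES, STATE_NAMES + NSTATE);
}

// [[Rcpp::export]]
CharacterVector cpp_current_names() {
  return CharacterVector(CUR_NAMES, CUR_NAMES + NCUR);
}

// [[Rcpp::export]]
NumericVector cpp_cell_currents(NumericVector state, NumericVector params) {
  check_state(state);
  Par p = make_par(params);
  NumericVector out(NCUR);
  crn_currents(p, REAL(state), REAL(out));
  // force and troponin flux for completeness
  double dTropTot, dsm[11];
  out[cForce] = rice_derivs(p, REAL(state), state[iCai] * 1000.0, 0,
                            state[iSL], dsm, &dTropTot);
  out[cdTropTot] = dTropTot;
  out.attr("names") = cpp_current_names();
  return out;
}

// [[Rcpp::export]]
List cpp_cell_derivs(NumericVector state, NumericVector params,
                     double i_stim = 0.0, int mech_mode = 1,
                     double sl_set = NA_REAL) {
  check_state(state);
  Par p = make_par(params);
  if (!R_finite(sl_set)) sl_set = p.SL0;
  NumericVector d(NSTATE), cur(NCUR);
  cell_derivs(p, REAL(state), i_stim, mech_mode, sl_set, REAL(d), REAL(cur));
  d.attr("names") = cpp_state_names();
  cur.attr("names") = cpp_current_names();
  return List::create(_["derivs"] = d, _["currents"] = cur);
}

// [[Rcpp::export]]
List cpp_rice_derivs(NumericVector state, NumericVector params, double ca_uM,
                     int mech_mode = 0, double sl_set = NA_REAL) {
  check_state(state);
  if (ca_uM < 0) stop("calcium concentration must be non-negative");
  Par p = make_par(params);
  if (!R_finite(sl_set)) sl_set = p.SL0;
  double dsm[11], dTropTot;
  double force = rice_derivs(p, REAL(state), ca_uM, mech_mode, sl_set, dsm,
                             &dTropTot);
  NumericVector d(11);
  for (int k = 0; k < 11; ++k) d[k] = dsm[k];
  d.attr("names") = CharacterVector(STATE_NAMES + iNNoXB,
                                    STATE_NAMES + NSTATE);
  return List::create(_["derivs"] = d, _["force"] = force,
                      _["dTropTot"] = dTropTot);
}

// Paced run. Stimulus: rectangular current of given amplitude (pA/pF,
// positive = depolarising, applied as an inward current) and duration at
// each onset time. Records every record_dt from record_start.
// [[Rcpp::export]]
List cpp_cell_run(NumericVector state, NumericVector params,
                  NumericVector stim_times, double stim_dur, double stim_amp,
                  double t_end, double dt, double record_start,
                  double record_dt, int mech_mode = 1,
                  bool stim_in_ki = true, bool record_currents = true,
                  double sl_set = NA_REAL) {
  check_state(state);
  Par p = make_par(params);
  if (dt <= 0) stop("dt must be positive");
  if (!R_finite(sl_set)) sl_set = state[iSL];
  std::vector<double> s(REAL(state), REAL(state) + NSTATE);
  double cur[NCUR];

  const long nstep = (long)std::ceil(t_end / dt - 1e-9);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  const int ncol_cur = record_currents ? NCUR : 0;
  std::vector<double> rec;
  rec.reserve(4096);
  GateTrack track;
  track.init();

  int si = 0; // next stimulus index
  const int nstim = stim_times.size();
  for (long it = 0; it < nstep; ++it) {
    const double t = it * dt;
    while (si < nstim && t >= stim_times[si] + stim_dur) ++si;
    double Ist = 0.0;
    if (si < nstim && t >= stim_times[si] && t < stim_times[si] + stim_dur)
      Ist = -stim_amp;
    if (t + 1e-9 >= record_start && it % rec_every == 0) {
      rec.push_back(t);
      for (int k = 0; k < NSTATE; ++k) rec.push_back(s[k]);
      if (record_currents) {
        crn_currents(p, s.data(), cur);
        double dTropTot, dsm[11];
        cur[cForce] = rice_derivs(p, s.data(), s[iCai] * 1000.0, mech_mode,
                                  sl_set, dsm, &dTropTot);
        cur[cdTropTot] = dTropTot;
        for (int k = 0; k < NCUR; ++k) rec.push_back(cur[k]);
      }
    }
    cell_step(p, s.data(), dt, Ist, mech_mode, sl_set, stim_in_ki, cur);
    track.update(s.data());
    if (!std::isfinite(s[iV]))
      stop("membrane potential became non-finite at t = %.3f ms", t);
  }

  const int ncol = 1 + NSTATE + ncol_cur;
  const long nrow = (long)rec.size() / ncol;
  NumericMatrix trace(nrow, ncol);
  for (long r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) trace(r, c) = rec[r * ncol + c];
  CharacterVector cn(ncol);
  cn[0] = "t";
  for (int k = 0; k < NSTATE; ++k) cn[1 + k] = STATE_NAMES[k];
  if (record_currents)
    for (int k = 0; k < NCUR; ++k) cn[1 + NSTATE + k] = CUR_NAMES[k];
  colnames(trace) = cn;

  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = cpp_state_names();
  NumericVector gmin(track.gmin, track.gmin + 15);
  NumericVector gmax(track.gmax, track.gmax + 15);
  return List::create(_["trace"] = trace, _["final_state"] = fin,
                      _["gate_min"] = gmin, _["gate_max"] = gmax,
                      _["conc_min"] = track.cmin);
}

// Voltage clamp: hold at v_hold until t_step, then step to v_step.
// Gates/concentrations evolve; V is prescribed. Used for current
// isolation checks (e.g. peak I_CaL scaling).
// [[Rcpp::export]]
List cpp_cell_vclamp(NumericVector state, NumericVector params,
                     double v_hold, double v_step, double t_step,
                     double t_end, double dt, double record_dt) {
  check_state(state);
  Par p = make_par(params);
  std::vector<double> s(REAL(state), REAL(state) + NSTATE);
  double cur[NCUR];
  const long nstep = (long)std::ceil(t_end / dt - 1e-9);
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  std::vector<double> rec;
  for (long it = 0; it < nstep; ++it) {
    const double t = it * dt;
    s[iV] = (t < t_step) ? v_hold : v_step;
    if (it % rec_every == 0) {
      crn_currents(p, s.data(), cur);
      rec.push_back(t);
      for (int k = 0; k < NCUR; ++k) rec.push_back(cur[k]);
    }
    cell_step(p, s.data(), dt, 0.0, 0, s[iSL], false, cur);
  }
  const int ncol = 1 + NCUR;
  const long nrow = (long)rec.size() / ncol;
  NumericMatrix trace(nrow, ncol);
  for (long r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) trace(r, c) = rec[r * ncol + c];
  CharacterVector cn(ncol);
  cn[0] = "t";
  for (int k = 0; k < NCUR; ++k) cn[1 + k] = CUR_NAMES[k];
  colnames(trace) = cn;
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = cpp_state_names();
  return List::create(_["trace"] = trace, _["final_state"] = fin);
}

// Myofilament-only integration at clamped Ca (microM) and fixed or free SL.
// Returns force at t_end (steady state if t_end long enough).
// [[Rcpp::export]]
List cpp_rice_clamp(NumericVector params, double ca_uM, double sl,
                    double t_end, double dt, int mech_mode = 0) {
  Par p = make_par(params);
  if (ca_uM < 0) stop("calcium concentration must be non-negative");
  std::vector<double> s(NSTATE, 0.0);
  s[iNNoXB] = 0.99; s[iPNoXB] = 0.01; s[iN] = 0.98;
  s[iXBprer] = 0.01; s[iXBpostr] = 0.01;
  s[iSL] = sl; s[ixXBprer] = 0.0; s[ixXBpostr] = p.x_0;
  s[iTRPNCaL] = 0.01; s[iTRPNCaH] = 0.1; s[iintf] = 0.0;
  double force = 0.0, dTropTot, dsm[11];
  const long nstep = (long)std::ceil(t_end / dt);
  for (long it = 0; it < nstep; ++it) {
    force = rice_derivs(p, s.data(), ca_uM, mech_mode, sl, dsm, &dTropTot);
    for (int k = 0; k < 11; ++k) s[iNNoXB + k] += dt * dsm[k];
    for (int k : {iNNoXB, iPNoXB, iN, iXBprer, iXBpostr, iTRPNCaL,
                  iTRPNCaH}) {
      if (s[k] < 0.0) s[k] = 0.0;
      if (s[k] > 1.0) s[k] = 1.0;
    }
    if (s[iSL] < p.SLmin) s[iSL] = p.SLmin;
    if (s[iSL] > p.SLmax) s[iSL] = p.SLmax;
  }
  NumericVector fin(s.begin(), s.end());
  fin.attr("names") = cpp_state_names();
  return List::create(_["force"] = force, _["final_state"] = fin,
                      _["SL"] = s[iSL]);
}
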
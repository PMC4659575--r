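// Coupled human atrial cell model: CRN electrophysiology + Rice myofilament
// mechanics, linked through dynamic troponin Ca2+ buffering.
// All rates in ms^-1, potentials in mV, concentrations in mM (EP side) and
// microM (myofilament side), currents in pA/pF, volumes in micrometre^3.
#ifndef ATRIAMECH_CELLMODEL_H
#define ATRIAMECH_CELLMODEL_H

#include <cmath>
#include <algorithm>

namespace atriamech {

constexpr int NPAR = 87;
constexpr int NSTATE = 32;
constexpr int NCUR = 19;

// state indices
enum {
  iV = 0, im, ih, ij, ioa, ioi, iua, iui, ixr, ixs, id_, if_, ifca,
  iu, iv, iw, iNai, iKi, iCai, iCaup, iCarel,
  iNNoXB, iPNoXB, iN, iXBprer, iXBpostr, iSL, ixXBprer, ixXBpostr,
  iTRPNCaL, iTRPNCaH, iintf
};

// current/flux output indices
enum {
  cINa = 0, cIK1, cIto, cIKur, cIKr, cIKs, cICaL, cIpCa, cINaCa, cIbNa,
  cIbCa, cINaK, cIrel, cItr, cIup, cIleak, cIion, cForce, cdTropTot
};

struct Par {
  // electrophysiology
  double Cm, F, Rgas, T, V_i, V_up, V_rel, Na_o, K_o, Ca_o;
  double g_Na, g_K1, g_to, g_Kr, g_Ks, g_CaL, g_Kur_sc, g_bNa, g_bCa;
  double i_NaK_max, Km_Na_i, Km_K_o;
  double i_NaCa_max, K_mNa, K_mCa, k_sat, gma;
  double i_pCa_max, Km_pCa;
  double k_rel, i_up_max, K_up, k_leak, Ca_up_max;
  double CMDN_max, Km_CMDN, CSQN_max, Km_CSQN;
  double tau_tr, tau_f_Ca, tau_u, K_Q10;
  // myofilament
  double kon, koffL, koffH, TrpnTot, perm50, nperm, kn_p, kp_n;
  double fapp, gapp, gslmod, hf, hfmdc, hb, hbmdc, gxb, sigmap, sigman;
  double xPsi, x_0, xbmodsp, TmpC;
  double Qkon, Qkoff, Qkn_p, Qkp_n, Qfapp, Qgapp, Qhf, Qhb, Qgxb;
  double SLmin, SLmax, len_thick, len_hbare, len_thin, SL0;
  double PCon_t, PExp_t, SL_c, PCon_c, PExp_c, visc, mass, KSE;
  // derived (filled by par_prepare)
  double RTF;                     // R*T/F
  double konT, koffLT, koffHT, kn_pT, kp_nT;
  double fappT, gappT, hfT, hbT, gxbT; // temperature-adjusted base rates
  double SSXBprer, SSXBpostr;      // steady-state duty fractions
  double Fnorm_den;                // x_0 * SSXBpostr
};

inline void par_from_vec(const double* v, Par& p) {
  int k = 0;
  p.Cm = v[k++]; p.F = v[k++]; p.Rgas = v[k++]; p.T = v[k++];
  p.V_i = v[k++]; p.V_up = v[k++]; p.V_rel = v[k++];
  p.Na_o = v[k++]; p.K_o = v[k++]; p.Ca_o = v[k++];
  p.g_Na = v[k++]; p.g_K1 = v[k++]; p.g_to = v[k++]; p.g_Kr = v[k++];
  p.g_Ks = v[k++]; p.g_CaL = v[k++]; p.g_Kur_sc = v[k++];
  p.g_bNa = v[k++]; p.g_bCa = v[k++];
  p.i_NaK_max = v[k++]; p.Km_Na_i = v[k++]; p.Km_K_o = v[k++];
  p.i_NaCa_max = v[k++]; p.K_mNa = v[k++]; p.K_mCa = v[k++];
  p.k_sat = v[k++]; p.gma = v[k++];
  p.i_pCa_max = v[k++]; p.Km_pCa = v[k++];
  p.k_rel = v[k++]; p.i_up_max = v[k++]; p.K_up = v[k++];
  p.k_leak = v[k++]; p.Ca_up_max = v[k++];
  p.CMDN_max = v[k++]; p.Km_CMDN = v[k++]; p.CSQN_max = v[k++];
  p.Km_CSQN = v[k++];
  p.tau_tr = v[k++]; p.tau_f_Ca = v[k++]; p.tau_u = v[k++]; p.K_Q10 = v[k++];
  p.kon = v[k++]; p.koffL = v[k++]; p.koffH = v[k++]; p.TrpnTot = v[k++];
  p.perm50 = v[k++]; p.nperm = v[k++]; p.kn_p = v[k++]; p.kp_n = v[k++];
  p.fapp = v[k++]; p.gapp = v[k++]; p.gslmod = v[k++]; p.hf = v[k++];
  p.hfmdc = v[k++]; p.hb = v[k++]; p.hbmdc = v[k++]; p.gxb = v[k++];
  p.sigmap = v[k++]; p.sigman = v[k++];
  p.xPsi = v[k++]; p.x_0 = v[k++]; p.xbmodsp = v[k++]; p.TmpC = v[k++];
  p.Qkon = v[k++]; p.Qkoff = v[k++]; p.Qkn_p = v[k++]; p.Qkp_n = v[k++];
  p.Qfapp = v[k++]; p.Qgapp = v[k++]; p.Qhf = v[k++]; p.Qhb = v[k++];
  p.Qgxb = v[k++];
  p.SLmin = v[k++]; p.SLmax = v[k++]; p.len_thick = v[k++];
  p.len_hbare = v[k++]; p.len_thin = v[k++]; p.SL0 = v[k++];
  p.PCon_t = v[k++]; p.PExp_t = v[k++]; p.SL_c = v[k++];
  p.PCon_c = v[k++]; p.PExp_c = v[k++]; p.visc = v[k++]; p.mass = v[k++];
  p.KSE = v[k++];
}

inline void par_prepare(Par& p) {
  p.RTF = p.Rgas * p.T / p.F;
  const double tf = (p.TmpC - 37.0) / 10.0;
  p.konT = p.kon * std::pow(p.Qkon, tf);
  p.koffLT = p.koffL * std::pow(p.Qkoff, tf);
  p.koffHT = p.koffH * std::pow(p.Qkoff, tf);
  p.kn_pT = p.kn_p * std::pow(p.Qkn_p, tf);
  p.kp_nT = p.kp_n * std::pow(p.Qkp_n, tf);
  p.fappT = p.fapp * p.xbmodsp * std::pow(p.Qfapp, tf);
  p.gappT = p.gapp * p.xbmodsp * std::pow(p.Qgapp, tf);
  p.hfT = p.hf * p.xbmodsp * std::pow(p.Qhf, tf);
  p.hbT = p.hb * p.xbmodsp * std::pow(p.Qhb, tf);
  p.gxbT = p.gxb * p.xbmodsp * std::pow(p.Qgxb, tf);
  // steady-state duty fractions of the 3-state crossbridge cycle at full
  // permissivity and unstrained rates: used for strain ODE scaling and
  // force normalisation.
  const double rB = p.hfT / (p.hbT + p.gxbT);
  const double A = p.fappT /
    (p.fappT * (1.0 + rB) + p.gappT + p.hfT - p.hbT * rB);
  p.SSXBprer = A;
  p.SSXBpostr = rB * A;
  p.Fnorm_den = p.x_0 * p.SSXBpostr;
}

struct GateUpd { double inf, tau; };

// guarded x/(1-exp(-x/s)) style helpers
inline double safe_ratio(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// Hodgkin-Huxley gate steady states and time constants at potential V.
// Equations follow the CRN human atrial cell model.
inline void crn_gates(const Par& p, double V, double Cai, double Fn,
                      GateUpd* g) {
  // m
  double am = std::fabs(V + 47.13) < 1e-8
    ? 3.2 : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  g[0].inf = am / (am + bm); g[0].tau = 1.0 / (am + bm);
  // h, j
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
         * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  g[1].inf = ah / (ah + bh); g[1].tau = 1.0 / (ah + bh);
  g[2].inf = aj / (aj + bj); g[2].tau = 1.0 / (aj + bj);
  // oa, oi (Ito), with Q10 = K_Q10
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) +
                       std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  g[3].inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  g[3].tau = 1.0 / ((aoa + boa) * p.K_Q10);
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  g[4].inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  g[4].tau = 1.0 / ((aoi + boi) * p.K_Q10);
  // ua, ui (IKur)
  double aua = aoa, bua = boa;
  g[5].inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  g[5].tau = 1.0 / ((aua + bua) * p.K_Q10);
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  g[6].inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  g[6].tau = 1.0 / ((aui + bui) * p.K_Q10);
  // xr
  double axr = std::fabs(V + 14.1) < 1e-8
    ? 0.0015 : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double bxr = std::fabs(V - 3.3328) < 1e-8
    ? 3.7836118e-4
    : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  g[7].inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  g[7].tau = 1.0 / (axr + bxr);
  // xs
  double axs = std::fabs(V - 19.9) < 1e-8
    ? 6.8e-4 : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double bxs = std::fabs(V - 19.9) < 1e-8
    ? 3.15e-4 : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  g[8].inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  g[8].tau = 0.5 / (axs + bxs);
  // d
  double x = V + 10.0;
  g[9].inf = 1.0 / (1.0 + std::exp(-x / 8.0));
  g[9].tau = std::fabs(x) < 1e-8
    ? 1.0 / (6.24 * 0.07)
    : (1.0 - std::exp(-x / 6.24)) /
      (0.035 * x * (1.0 + std::exp(-x / 6.24)));
  // f
  g[10].inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  g[10].tau = 9.0 /
    (0.0197 * std::exp(-0.0337 * 0.0337 * x * x) + 0.02);
  // fCa
  g[11].inf = 1.0 / (1.0 + Cai / 0.00035);
  g[11].tau = p.tau_f_Ca;
  // u, v (SR release), from Fn
  double e1 = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  g[12].inf = 1.0 / (1.0 + e1);
  g[12].tau = p.tau_u;
  g[13].inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  g[13].tau = 1.91 + 2.09 / (1.0 + e1);
  // w
  double y = V - 7.9;
  g[14].inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  g[14].tau = std::fabs(y) < 1e-8
    ? 6.0 / 6.5
    : 6.0 * (1.0 - std::exp(-y / 5.0)) /
      ((1.0 + 0.3 * std::exp(-y / 5.0)) * y);
}

// Transmembrane currents (pA/pF) and SR fluxes (mM/ms). cur must hold NCUR.
inline void crn_currents(const Par& p, const double* s, double* cur) {
  const double V = s[iV], Nai = s[iNai], Ki = s[iKi], Cai = s[iCai];
  const double ENa = p.RTF * std::log(p.Na_o / Nai);
  const double EK = p.RTF * std::log(p.K_o / Ki);
  const double ECa = 0.5 * p.RTF * std::log(p.Ca_o / Cai);
  cur[cINa] = p.g_Na * s[im] * s[im] * s[im] * s[ih] * s[ij] * (V - ENa);
  cur[cIK1] = p.g_K1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  cur[cIto] = p.g_to * s[ioa] * s[ioa] * s[ioa] * s[ioi] * (V - EK);
  const double gkur = p.g_Kur_sc *
    (0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0)));
  cur[cIKur] = gkur * s[iua] * s[iua] * s[iua] * s[iui] * (V - EK);
  cur[cIKr] = p.g_Kr * s[ixr] * (V - EK) /
    (1.0 + std::exp((V + 15.0) / 22.4));
  cur[cIKs] = p.g_Ks * s[ixs] * s[ixs] * (V - EK);
  cur[cICaL] = p.g_CaL * s[id_] * s[if_] * s[ifca] * (V - 65.0);
  cur[cIpCa] = p.i_pCa_max * Cai / (p.Km_pCa + Cai);
  const double ef = std::exp(p.gma * V / p.RTF);
  const double er = std::exp((p.gma - 1.0) * V / p.RTF);
  cur[cINaCa] = p.i_NaCa_max *
    (ef * Nai * Nai * Nai * p.Ca_o - er * p.Na_o * p.Na_o * p.Na_o * Cai) /
    ((p.K_mNa * p.K_mNa * p.K_mNa + p.Na_o * p.Na_o * p.Na_o) *
     (p.K_mCa + p.Ca_o) * (1.0 + p.k_sat * er));
  cur[cIbNa] = p.g_bNa * (V - ENa);
  cur[cIbCa] = p.g_bCa * (V - ECa);
  const double sig = (std::exp(p.Na_o / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / p.RTF) +
                             0.0365 * sig * std::exp(-V / p.RTF));
  cur[cINaK] = p.i_NaK_max * fNaK *
    (1.0 / (1.0 + std::pow(p.Km_Na_i / Nai, 1.5))) *
    (p.K_o / (p.K_o + p.Km_K_o));
  // SR fluxes
  cur[cIrel] = p.k_rel * s[iu] * s[iu] * s[iv] * s[iw] * (s[iCarel] - Cai);
  cur[cItr] = (s[iCaup] - s[iCarel]) / p.tau_tr;
  cur[cIup] = p.i_up_max / (1.0 + p.K_up / Cai);
  cur[cIleak] = p.k_leak * s[iCaup];
  cur[cIion] = cur[cINa] + cur[cIK1] + cur[cIto] + cur[cIKur] + cur[cIKr] +
    cur[cIKs] + cur[cICaL] + cur[cIpCa] + cur[cINaK] + cur[cINaCa] +
    cur[cIbNa] + cur[cIbCa];
}

inline double sgn(double x) { return (x > 0) - (x < 0); }

// Myofilament derivatives. Ca in microM. mode: 0 isosarcometric, 1 unloaded
// shortening (SL dynamic). SLset: resting/attachment length for the series
// viscoelastic load. ds receives derivatives for the 11 myofilament states
// (same ordering as in the full state vector). Returns normalised active
// force; *dTropTot gets the total troponin-bound Ca flux (microM/ms).
inline double rice_derivs(const Par& p, const double* s, double Ca_uM,
                          int mode, double SLset, double* ds,
                          double* dTropTot) {
  const double SL = s[iSL];
  // thick/thin filament overlap
  const double sovr_ze = std::min(p.len_thick / 2.0, SL / 2.0);
  const double sovr_cle = std::max(SL / 2.0 - (SL - p.len_thin),
                                   p.len_hbare / 2.0);
  const double len_sovr = std::max(sovr_ze - sovr_cle, 0.0);
  const double SOVFThick = 2.0 * len_sovr / (p.len_thick - p.len_hbare);
  const double SOVFThin = len_sovr / p.len_thin;
  const double dze = (SL < p.len_thick) ? 0.5 : 0.0;
  const double dcle = (p.len_thin - SL / 2.0 > p.len_hbare / 2.0) ? -0.5 : 0.0;
  const double dSOVFThin_dSL = (len_sovr > 0.0) ? (dze - dcle) / p.len_thin
                                                : 0.0;
  // troponin Ca binding (low/high affinity)
  const double TRPNCaL = s[iTRPNCaL], TRPNCaH = s[iTRPNCaH];
  const double dTRPNCaL = p.konT * Ca_uM * (1.0 - TRPNCaL) -
    p.koffLT * TRPNCaL;
  const double dTRPNCaH = p.konT * Ca_uM * (1.0 - TRPNCaH) -
    p.koffHT * TRPNCaH;
  // permissivity
  const double Tropreg = (1.0 - SOVFThin) * TRPNCaL + SOVFThin * TRPNCaH;
  const double permtot =
    std::sqrt(1.0 / (1.0 + std::pow(p.perm50 / std::max(Tropreg, 1e-12),
                                    p.nperm)));
  const double inprmt = std::min(1.0 / permtot, 100.0);
  ds[iNNoXB - iNNoXB] = -p.kn_pT * permtot * s[iNNoXB] +
    p.kp_nT * inprmt * s[iPNoXB];
  ds[iPNoXB - iNNoXB] = -ds[iNNoXB - iNNoXB];
  const double N = s[iN], XBprer = s[iXBprer], XBpostr = s[iXBpostr];
  const double P = std::max(1.0 - N - XBprer - XBpostr, 0.0);
  ds[iN - iNNoXB] = -p.kn_pT * permtot * N + p.kp_nT * inprmt * P;
  // strain-modulated crossbridge rates
  const double xprer = s[ixXBprer], xpostr = s[ixXBpostr];
  const double gapslmd = 1.0 + (1.0 - SOVFThick) * p.gslmod;
  const double fappT = p.fappT;
  const double gappT = p.gappT * gapslmd;
  const double hfmd = std::exp(-sgn(xprer) * p.hfmdc *
                               (xprer / p.x_0) * (xprer / p.x_0));
  const double hbmd = std::exp(sgn(xpostr - p.x_0) * p.hbmdc *
                               ((xpostr - p.x_0) / p.x_0) *
                               ((xpostr - p.x_0) / p.x_0));
  const double hfT = p.hfT * hfmd;
  const double hbT = p.hbT * hbmd;
  const double gxbmd = (xpostr < p.x_0)
    ? std::exp(p.sigmap * ((p.x_0 - xpostr) / p.x_0) *
               ((p.x_0 - xpostr) / p.x_0))
    : std::exp(p.sigman * ((xpostr - p.x_0) / p.x_0) *
               ((xpostr - p.x_0) / p.x_0));
  const double gxbT = p.gxbT * gxbmd;
  const double dXBprer = fappT * P - gappT * XBprer - hfT * XBprer +
    hbT * XBpostr;
  const double dXBpostr = hfT * XBprer - (hbT + gxbT) * XBpostr;
  ds[iXBprer - iNNoXB] = dXBprer;
  ds[iXBpostr - iNNoXB] = dXBpostr;
  // normalised active and passive force
  const double force = SOVFThick * (xpostr * XBpostr + xprer * XBprer) /
    p.Fnorm_den;
  double pp = sgn(SL - p.SL0) * p.PCon_t *
    (std::exp(p.PExp_t * std::fabs(SL - p.SL0)) - 1.0);
  if (SL > p.SL_c) pp += p.PCon_c * (std::exp(p.PExp_c * (SL - p.SL_c)) - 1.0);
  double preload = sgn(SLset - p.SL0) * p.PCon_t *
    (std::exp(p.PExp_t * std::fabs(SLset - p.SL0)) - 1.0);
  double dSL = 0.0, dintf = 0.0;
  if (mode == 1) {
    dSL = (s[iintf] + (SLset - SL) * p.visc) / p.mass;
    if ((SL <= p.SLmin && dSL < 0) || (SL >= p.SLmax && dSL > 0)) dSL = 0.0;
    // series-elastic internal load resists shortening (compliant boundary)
    dintf = -(force + pp + p.KSE * (SL - SLset) - preload);
  }
  ds[iSL - iNNoXB] = dSL;
  ds[iintf - iNNoXB] = dintf;
  // mean crossbridge strain dynamics, scaled by steady-state duty fractions
  ds[ixXBprer - iNNoXB] = 0.5 * dSL + (p.xPsi / p.SSXBprer) *
    (-fappT * xprer + hbT * (xpostr - p.x_0 - xprer));
  ds[ixXBpostr - iNNoXB] = 0.5 * dSL + (p.xPsi / p.SSXBpostr) *
    hfT * (xprer + p.x_0 - xpostr);
  ds[iTRPNCaL - iNNoXB] = dTRPNCaL;
  ds[iTRPNCaH - iNNoXB] = dTRPNCaH;
  // total troponin-bound Ca and its rate (chain rule incl. overlap change)
  const double SSsum = p.SSXBprer + p.SSXBpostr;
  const double FrSBXB = (XBprer + XBpostr) / SSsum;
  const double dFrSBXB = (dXBprer + dXBpostr) / SSsum;
  const double mixH = FrSBXB * TRPNCaH + (1.0 - FrSBXB) * TRPNCaL;
  const double dmixH = dFrSBXB * (TRPNCaH - TRPNCaL) + FrSBXB * dTRPNCaH +
    (1.0 - FrSBXB) * dTRPNCaL;
  *dTropTot = p.TrpnTot *
    ((1.0 - SOVFThin) * dTRPNCaL + SOVFThin * dmixH +
     dSOVFThin_dSL * dSL * (mixH - TRPNCaL));
  return force;
}

// Full right-hand side (explicit form) used by the reference stiff solver
// cross-check; gate derivatives as (inf - g)/tau.
inline void cell_derivs(const Par& p, const double* s, double Ist,
                        int mech_mode, double SLset, double* dsdt,
                        double* cur) {
  crn_currents(p, s, cur);
  // SR release regulation variable Fn (amperes-scale composite)
  const double Fn = 1e-12 * p.V_rel * cur[cIrel] -
    (5e-13 / p.F) * (0.5 * cur[cICaL] - 0.2 * cur[cINaCa]) * p.Cm;
  GateUpd g[15];
  crn_gates(p, s[iV], s[iCai], Fn, g);
  dsdt[iV] = -(cur[cIion] + Ist);
  for (int k = 0; k < 15; ++k)
    dsdt[im + k] = (g[k].inf - s[im + k]) / g[k].tau;
  const double FVi = p.F * p.V_i;
  dsdt[iNai] = (-3.0 * cur[cINaK] - 3.0 * cur[cINaCa] - cur[cIbNa] -
                cur[cINa]) * p.Cm / FVi;
  dsdt[iKi] = (2.0 * cur[cINaK] - cur[cIK1] - cur[cIto] - cur[cIKur] -
               cur[cIKr] - cur[cIKs] - Ist) * p.Cm / FVi;
  // myofilament (Ca in microM)
  double dTropTot;
  double dsm[11];
  cur[cForce] = rice_derivs(p, s, s[iCai] * 1000.0, mech_mode, SLset, dsm,
                            &dTropTot);
  for (int k = 0; k < 11; ++k) dsdt[iNNoXB + k] = dsm[k];
  cur[cdTropTot] = dTropTot;
  // myoplasmic Ca2+ balance: sarcolemmal + SR + troponin terms under
  // instantaneous calmodulin buffering
  const double Cai = s[iCai];
  const double bcmdn = 1.0 /
    (1.0 + p.CMDN_max * p.Km_CMDN /
           ((Cai + p.Km_CMDN) * (Cai + p.Km_CMDN)));
  dsdt[iCai] = bcmdn *
    (-p.Cm * (cur[cICaL] + cur[cIbCa] + cur[cIpCa] - 2.0 * cur[cINaCa]) /
       (2.0 * p.V_i * p.F) +
     (p.V_up * (cur[cIleak] - cur[cIup]) + cur[cIrel] * p.V_rel) / p.V_i -
     dTropTot / 1000.0);
  dsdt[iCaup] = cur[cIup] - cur[cIleak] - cur[cItr] * p.V_rel / p.V_up;
  const double Carel = s[iCarel];
  const double bcsqn = 1.0 /
    (1.0 + p.CSQN_max * p.Km_CSQN /
           ((Carel + p.Km_CSQN) * (Carel + p.Km_CSQN)));
  dsdt[iCarel] = bcsqn * (cur[cItr] - cur[cIrel]);
}

struct GateTrack {
  double gmin[15], gmax[15];
  double cmin;  // min over concentrations
  void init() {
    for (int k = 0; k < 15; ++k) { gmin[k] = 1e300; gmax[k] = -1e300; }
    cmin = 1e300;
  }
  void update(const double* s) {
    for (int k = 0; k < 15; ++k) {
      if (s[im + k] < gmin[k]) gmin[k] = s[im + k];
      if (s[im + k] > gmax[k]) gmax[k] = s[im + k];
    }
    for (int k = iNai; k <= iCarel; ++k) if (s[k] < cmin) cmin = s[k];
  }
};

// One explicit/exponential time step:
//  - V, Na_i, K_i, Ca_i, Ca_up, myofilament states: forward Euler
//  - 15 HH gates: Rush-Larsen exponential update
//  - Ca_rel: exponential update of the frozen-coefficient linear ODE
//    (stiff under RyR upscaling)
// stim_in_Ki: assign stimulus charge to K+ so long pacing conserves charge.
inline void cell_step(const Par& p, double* s, double dt, double Ist,
                      int mech_mode, double SLset, bool stim_in_Ki,
                      double* cur) {
  crn_currents(p, s, cur);
  const double Fn = 1e-12 * p.V_rel * cur[cIrel] -
    (5e-13 / p.F) * (0.5 * cur[cICaL] - 0.2 * cur[cINaCa]) * p.Cm;
  GateUpd g[15];
  crn_gates(p, s[iV], s[iCai], Fn, g);
  double dTropTot, dsm[11];
  cur[cForce] = rice_derivs(p, s, s[iCai] * 1000.0, mech_mode, SLset, dsm,
                            &dTropTot);
  cur[cdTropTot] = dTropTot;

  const double FVi = p.F * p.V_i;
  s[iV] += dt * (-(cur[cIion] + Ist));
  for (int k = 0; k < 15; ++k)
    s[im + k] = g[k].inf + (s[im + k] - g[k].inf) * std::exp(-dt / g[k].tau);
  s[iNai] += dt * (-3.0 * cur[cINaK] - 3.0 * cur[cINaCa] - cur[cIbNa] -
                   cur[cINa]) * p.Cm / FVi;
  s[iKi] += dt * (2.0 * cur[cINaK] - cur[cIK1] - cur[cIto] - cur[cIKur] -
                  cur[cIKr] - cur[cIKs] - (stim_in_Ki ? Ist : 0.0)) *
            p.Cm / FVi;
  const double Cai = s[iCai];
  const double bcmdn = 1.0 /
    (1.0 + p.CMDN_max * p.Km_CMDN /
           ((Cai + p.Km_CMDN) * (Cai + p.Km_CMDN)));
  s[iCai] += dt * bcmdn *
    (-p.Cm * (cur[cICaL] + cur[cIbCa] + cur[cIpCa] - 2.0 * cur[cINaCa]) /
       (2.0 * p.V_i * p.F) +
     (p.V_up * (cur[cIleak] - cur[cIup]) + cur[cIrel] * p.V_rel) / p.V_i -
     dTropTot / 1000.0);
  if (s[iCai] < 1e-7) s[iCai] = 1e-7;
  s[iCaup] += dt * (cur[cIup] - cur[cIleak] - cur[cItr] * p.V_rel / p.V_up);
  // exponential update for junctional SR Ca2+
  {
    const double Carel = s[iCarel];
    const double bcsqn = 1.0 /
      (1.0 + p.CSQN_max * p.Km_CSQN /
             ((Carel + p.Km_CSQN) * (Carel + p.Km_CSQN)));
    const double krel_open = p.k_rel * s[iu] * s[iu] * s[iv] * s[iw];
    const double B = bcsqn * (1.0 / p.tau_tr + krel_open);
    const double A = bcsqn * (s[iCaup] / p.tau_tr + krel_open * s[iCai]);
    const double Xinf = A / B;
    s[iCarel] = Xinf + (Carel - Xinf) * std::exp(-B * dt);
  }
  // myofilament states: forward Euler except SL, whose viscous relaxation
  // (time constant mass/visc) is stiff and takes an exponential update of
  // the frozen-coefficient linear form dSL/dt = a - (visc/mass) SL.
  for (int k = 0; k < 11; ++k)
    if (iNNoXB + k != iSL) s[iNNoXB + k] += dt * dsm[k];
  if (mech_mode == 1) {
    const double b = p.visc / p.mass;
    const double SLinf = SLset + s[iintf] / p.visc;
    double SLn = SLinf + (s[iSL] - SLinf) * std::exp(-b * dt);
    s[iSL] = SLn;
  }
  // keep myofilament fractions physical
  for (int k : {iNNoXB, iPNoXB, iN, iXBprer, iXBpostr, iTRPNCaL, iTRPNCaH}) {
    if (s[k] < 0.0) s[k] = 0.0;
    if (s[k] > 1.0) s[k] = 1.0;
  }
  if (s[iSL] < p.SLmin) s[iSL] = p.SLmin;
  if (s[iSL] > p.SLmax) s[iSL] = p.SLmax;
}

} // namespace atriamech
#endif
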
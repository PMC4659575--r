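# Independent oracles used across the test suite.
#
# oracle_crn_currents() is a second, independently written R encoding of the
# CRN membrane currents / SR fluxes, used to cross-check the compiled
# implementation at arbitrary states.
# oracle_rice_steady_force() solves the myofilament steady state
# algebraically (no time integration).

oracle_crn_currents <- function(state, params) {
  s <- as.list(state)
  p <- as.list(params)
  RTF <- p$R * p$T / p$F
  ENa <- RTF * log(p$Na_o / s$Na_i)
  EK <- RTF * log(p$K_o / s$K_i)
  ECa <- RTF / 2 * log(p$Ca_o / s$Ca_i)
  INa <- p$g_Na * s$m^3 * s$h * s$j * (s$V - ENa)
  IK1 <- p$g_K1 * (s$V - EK) / (1 + exp(0.07 * (s$V + 80)))
  Ito <- p$g_to * s$oa^3 * s$oi * (s$V - EK)
  gkur <- p$g_Kur_sc * (0.005 + 0.05 / (1 + exp(-(s$V - 15) / 13)))
  IKur <- gkur * s$ua^3 * s$ui * (s$V - EK)
  IKr <- p$g_Kr * s$xr * (s$V - EK) / (1 + exp((s$V + 15) / 22.4))
  IKs <- p$g_Ks * s$xs^2 * (s$V - EK)
  ICaL <- p$g_CaL * s$d * s$f * s$fca * (s$V - 65)
  IpCa <- p$i_pCa_max * s$Ca_i / (p$Km_pCa + s$Ca_i)
  sig <- (exp(p$Na_o / 67.3) - 1) / 7
  fNaK <- (1 + 0.1245 * exp(-0.1 * s$V / RTF) +
             0.0365 * sig * exp(-s$V / RTF))^-1
  INaK <- p$i_NaK_max * fNaK / (1 + (p$Km_Na_i / s$Na_i)^1.5) *
    p$K_o / (p$K_o + p$Km_K_o)
  INaCa <- p$i_NaCa_max *
    (exp(p$gamma_ncx * s$V / RTF) * s$Na_i^3 * p$Ca_o -
       exp((p$gamma_ncx - 1) * s$V / RTF) * p$Na_o^3 * s$Ca_i) /
    ((p$K_mNa^3 + p$Na_o^3) * (p$K_mCa + p$Ca_o) *
       (1 + p$k_sat * exp((p$gamma_ncx - 1) * s$V / RTF)))
  IbNa <- p$g_bNa * (s$V - ENa)
  IbCa <- p$g_bCa * (s$V - ECa)
  Irel <- p$k_rel * s$u^2 * s$v * s$w * (s$Ca_rel - s$Ca_i)
  Itr <- (s$Ca_up - s$Ca_rel) / p$tau_tr
  Iup <- p$i_up_max / (1 + p$K_up / s$Ca_i)
  Ileak <- p$k_leak * s$Ca_up
  c(I_Na = INa, I_K1 = IK1, I_to = Ito, I_Kur = IKur, I_Kr = IKr,
    I_Ks = IKs, I_CaL = ICaL, I_pCa = IpCa, I_NaCa = INaCa, I_bNa = IbNa,
    I_bCa = IbCa, I_NaK = INaK, I_rel = Irel, I_tr = Itr, I_up = Iup,
    I_leak = Ileak,
    I_ion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
      INaCa + IbNa + IbCa)
}

# Sarcomere overlap fractions at a given SL
oracle_overlap <- function(SL, p) {
  ze <- min(p[["len_thick"]] / 2, SL / 2)
  cle <- max(SL / 2 - (SL - p[["len_thin"]]), p[["len_hbare"]] / 2)
  sovr <- max(ze - cle, 0)
  list(thick = 2 * sovr / (p[["len_thick"]] - p[["len_hbare"]]),
       thin = sovr / p[["len_thin"]])
}

# Temperature-adjusted myofilament rates (all ms^-1)
oracle_rice_rates <- function(p) {
  tf <- (p[["TmpC"]] - 37) / 10
  list(kon = p[["kon"]] * p[["Qkon"]]^tf,
       koffL = p[["koffL"]] * p[["Qkoff"]]^tf,
       koffH = p[["koffH"]] * p[["Qkoff"]]^tf,
       knp = p[["kn_p"]] * p[["Qkn_p"]]^tf,
       kpn = p[["kp_n"]] * p[["Qkp_n"]]^tf,
       fapp = p[["fapp"]] * p[["xbmodsp"]] * p[["Qfapp"]]^tf,
       gapp = p[["gapp"]] * p[["xbmodsp"]] * p[["Qgapp"]]^tf,
       hf = p[["hf"]] * p[["xbmodsp"]] * p[["Qhf"]]^tf,
       hb = p[["hb"]] * p[["xbmodsp"]] * p[["Qhb"]]^tf,
       gxb = p[["gxb"]] * p[["xbmodsp"]] * p[["Qgxb"]]^tf)
}

# Steady-state duty fractions of the unstrained crossbridge cycle
oracle_duty_fractions <- function(p) {
  r <- oracle_rice_rates(p)
  rB <- r$hf / (r$hb + r$gxb)
  A <- r$fapp / (r$fapp * (1 + rB) + r$gapp + r$hf - r$hb * rB)
  list(prer = A, postr = rB * A)
}

# Algebraic steady-state normalised force at clamped Ca (uM), fixed SL.
# At steady state the mean strains settle at (0, x_0), so all strain
# modulations are unity; only the overlap-dependent gapp correction stays.
oracle_rice_steady_force <- function(ca_uM, sl, p) {
  r <- oracle_rice_rates(p)
  ov <- oracle_overlap(sl, p)
  duty <- oracle_duty_fractions(p)
  trpL <- r$kon * ca_uM / (r$kon * ca_uM + r$koffL)
  trpH <- r$kon * ca_uM / (r$kon * ca_uM + r$koffH)
  reg <- (1 - ov$thin) * trpL + ov$thin * trpH
  permtot <- sqrt(1 / (1 + (p[["perm50"]] / reg)^p[["nperm"]]))
  inprmt <- min(1 / permtot, 100)
  knp <- r$knp * permtot
  kpn <- r$kpn * inprmt
  gapp <- r$gapp * (1 + (1 - ov$thick) * p[["gslmod"]])
  # linear balance for (N, P, A, B), N+P+A+B = 1
  # dN = -knp N + kpn P; A: fapp P = (gapp+hf) A - hb B; B = hf/(hb+gxb) A
  rB <- r$hf / (r$hb + r$gxb)
  # express P in terms of A: fapp P = (gapp + hf - hb rB) A
  Pa <- (gapp + r$hf - r$hb * rB) / r$fapp
  Na <- (kpn / knp) * Pa
  A <- 1 / (Na + Pa + 1 + rB)
  B <- rB * A
  ov$thick * B / duty$postr
}

# Total troponin-bound Ca (uM) of a state, matching the coupled balance
oracle_trop_total <- function(state, p) {
  ov <- oracle_overlap(state[["SL"]], p)
  duty <- oracle_duty_fractions(p)
  fr <- (state[["XBprer"]] + state[["XBpostr"]]) / (duty$prer + duty$postr)
  p[["TrpnTot"]] * ((1 - ov$thin) * state[["TRPNCaL"]] +
                      ov$thin * (fr * state[["TRPNCaH"]] +
                                   (1 - fr) * state[["TRPNCaL"]]))
}

# Total Ca content (amount units: mM * um^3) of a full state
oracle_total_ca <- function(state, p) {
  cai <- state[["Ca_i"]]
  cmdn <- p[["CMDN_max"]] * cai / (cai + p[["Km_CMDN"]])
  csqn <- p[["CSQN_max"]] * state[["Ca_rel"]] /
    (state[["Ca_rel"]] + p[["Km_CSQN"]])
  p[["V_i"]] * (cai + cmdn + oracle_trop_total(state, p) / 1000) +
    p[["V_up"]] * state[["Ca_up"]] +
    p[["V_rel"]] * (state[["Ca_rel"]] + csqn)
}

# short-protocol pacing used widely in the tests
test_protocol <- function(beats = 30, ...) {
  pacing_protocol(s1_count = beats, record_beats = 2, ...)
}

# internal entry points exercised directly by the tests
cpp_cell_run <- atriamech:::cpp_cell_run
cpp_cell_vclamp <- atriamech:::cpp_cell_vclamp
cpp_cell_derivs <- atriamech:::cpp_cell_derivs
cpp_rice_clamp <- atriamech:::cpp_rice_clamp
normalize_region <- atriamech:::normalize_region
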
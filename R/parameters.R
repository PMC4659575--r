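#' Base parameter set of the coupled atrial cell model
#'
#' Returns the full named parameter vector of the electromechanically coupled
#' human atrial cell: the CRN electrophysiology constants (maximal
#' conductances in nS/pF, pump/exchanger scalings, compartment volumes in
#' um^3, buffer constants in mM) and the Rice myofilament constants (rates in
#' ms^-1 at 37 C, lengths in um, normalised force units).
#'
#' @return A named numeric vector of class `cell_parameters`.
#' @export
#' @examples
#' p <- default_cell_parameters()
#' p[["g_CaL"]]
default_cell_parameters <- function() {
  p <- c(
    # membrane & physical constants
    Cm = 100, F = 96.4867, R = 8.3143, T = 310,
    V_i = 13668, V_up = 1109.52, V_rel = 96.48,
    Na_o = 140, K_o = 5.4, Ca_o = 1.8,
    # maximal conductances (nS/pF)
    g_Na = 7.8, g_K1 = 0.09, g_to = 0.1652, g_Kr = 0.029411765,
    g_Ks = 0.12941176, g_CaL = 0.12375, g_Kur_sc = 1.0,
    g_bNa = 0.0006744375, g_bCa = 0.001131,
    # Na/K pump
    i_NaK_max = 0.59933874, Km_Na_i = 10, Km_K_o = 1.5,
    # Na/Ca exchanger
    i_NaCa_max = 1600, K_mNa = 87.5, K_mCa = 1.38, k_sat = 0.1,
    gamma_ncx = 0.35,
    # sarcolemmal Ca pump
    i_pCa_max = 0.275, Km_pCa = 0.0005,
    # SR release / uptake / leak
    k_rel = 30, i_up_max = 0.005, K_up = 0.00092,
    k_leak = 0.005 / 15, Ca_up_max = 15,
    # Ca buffers
    CMDN_max = 0.05, Km_CMDN = 0.00238, CSQN_max = 10, Km_CSQN = 0.8,
    # time constants
    tau_tr = 180, tau_f_Ca = 2, tau_u = 8, K_Q10 = 3,
    # myofilament: troponin Ca binding (uM^-1 ms^-1 / ms^-1, 37 C)
    kon = 0.05, koffL = 0.25, koffH = 0.025, TrpnTot = 70,
    perm50 = 0.5, nperm = 15, kn_p = 0.5, kp_n = 0.05,
    # crossbridge cycling (ms^-1, 37 C)
    fapp = 0.5, gapp = 0.07, gslmod = 6, hf = 2, hfmdc = 5,
    hb = 0.4, hbmdc = 0, gxb = 0.07, sigmap = 8, sigman = 1,
    xPsi = 2, x_0 = 0.007, xbmodsp = 1, TmpC = 37,
    Qkon = 1.5, Qkoff = 1.3, Qkn_p = 1.6, Qkp_n = 1.6,
    Qfapp = 6.25, Qgapp = 2.5, Qhf = 6.25, Qhb = 6.25, Qgxb = 6.25,
    # sarcomere geometry (um) and passive elements
    SLmin = 1.4, SLmax = 2.4, len_thick = 1.65, len_hbare = 0.1,
    len_thin = 1.2, SL0 = 1.9,
    PCon_t = 0.002, PExp_t = 10, SL_c = 2.25, PCon_c = 0.02, PExp_c = 70,
    visc = 3, mass = 50, KSE = 1
  )
  stopifnot(identical(names(p), as.character(cpp_param_names())))
  class(p) <- c("cell_parameters", "numeric")
  p
}

#' Regional ionic-conductance scale factors
#'
#' One row per atrial region with the multiplicative factors applied to the
#' maximal conductances of I_Na, I_to, I_CaL, I_Kr and I_Kur relative to the
#' right-atrial base model. The RA/PM row is all ones. The pulmonary-vein
#' (PV) profile is not part of the published factor table; it follows the
#' shape used in the heterogeneity-modelling lineage (reduced I_CaL and I_to,
#' enhanced I_Kr) with magnitudes calibrated so the control PV model
#' reproduces the reported PV action potential duration. The BB-LA profile
#' mirrors BB-RA.
#'
#' @return A tibble with columns `region`, `g_Na`, `g_to`, `g_CaL`, `g_Kr`,
#'   `g_Kur`.
#' @export
region_profiles <- function() {
  tibble::tribble(
    ~region,         ~g_Na, ~g_to, ~g_CaL, ~g_Kr, ~g_Kur,
    "RA",             1.00,  1.00,   1.00,  1.00,   1.00,
    "CT-upper-endo",  1.00,  1.00,   1.67,  1.00,   1.00,
    "CT-upper-epi",   1.00,  0.50,   1.67,  1.00,   1.00,
    "CT-lower-endo",  1.00,  0.68,   1.67,  1.00,   1.00,
    "CT-lower-epi",   1.00,  0.34,   1.67,  1.00,   1.00,
    "BB-RA",          1.00,  1.00,   1.67,  1.00,   1.00,
    "BB-LA",          1.00,  1.00,   1.67,  1.00,   1.00,
    "TVR",            1.00,  1.00,   0.67,  1.53,   1.00,
    "MVR",            1.00,  1.00,   0.67,  2.44,   1.00,
    "RAA",            1.00,  0.68,   1.06,  1.00,   1.00,
    "LAA",            1.00,  0.68,   1.06,  1.60,   1.00,
    "LA",             1.00,  1.00,   1.00,  1.60,   1.00,
    "SEP",            1.50,  1.00,   0.25,  1.00,   0.67,
    "PV",             1.00,  0.75,   0.25,  1.90,   1.00
  )
}

#' AF electrical-remodelling factor sets
#'
#' Multiplicative factors applied on top of the regional profile to emulate
#' persistent-AF electrical remodelling: I_CaL -70%, I_Kur -50%, I_to -65%,
#' I_K1 +100%, I_Ks +100%, I_NaCa +55%, I_Kr unchanged, SERCA +50%,
#' RyR +300%, SR Ca leak +25% (I_KAch is absent from the base model, so its
#' "no change" entry is a no-op). The control profile is all ones.
#'
#' @return A tibble with one row per condition (`control`, `af`).
#' @export
remodeling_profiles <- function() {
  tibble::tribble(
    ~remodeling, ~I_CaL, ~I_Kur, ~I_to, ~I_K1, ~I_Ks, ~I_NaCa, ~I_Kr,
    ~SERCA, ~RyR, ~SR_leak,
    "control",     1.00,   1.00,  1.00,  1.00,  1.00,    1.00,  1.00,
    1.00, 1.00, 1.00,
    "af",          0.30,   0.50,  0.35,  2.00,  2.00,    1.55,  1.00,
    1.50, 4.00, 1.25
  )
}

normalize_region <- function(region) {
  aliases <- c("ra/pm" = "RA", "pm" = "RA", "ra" = "RA", "bbra" = "BB-RA",
               "bbla" = "BB-LA", "ct/bbla" = "BB-LA")
  key <- tolower(gsub("[ _]", "-", trimws(region)))
  if (key %in% names(aliases)) return(unname(aliases[[key]]))
  valid <- region_profiles()$region
  hit <- match(key, tolower(valid))
  if (is.na(hit)) {
    stop("unknown region '", region, "'; valid regions: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  valid[hit]
}

normalize_remodeling <- function(remodeling) {
  valid <- remodeling_profiles()$remodeling
  hit <- match(tolower(trimws(remodeling)), valid)
  if (is.na(hit)) {
    stop("unknown remodeling '", remodeling, "'; valid: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  valid[hit]
}

#' Build the parameter set for a regional, optionally AF-remodelled cell
#'
#' Applies the regional conductance factors and then the remodelling factors
#' multiplicatively to the base parameter set; each factor is applied exactly
#' once, so composing the two profiles equals applying their elementwise
#' product. The remodelling factors for SERCA, RyR, the SR leak and the
#' Na+/Ca2+ exchanger scale the corresponding maximal rates (`i_up_max`,
#' `k_rel`, `k_leak`, `i_NaCa_max`).
#'
#' @param region Region identifier (see [region_profiles()]); `"RA"` (alias
#'   `"RA/PM"`) is the baseline.
#' @param remodeling `"control"` or `"af"`.
#' @param overrides Optional named numeric vector of parameter overrides
#'   applied after the profiles (e.g. a custom PV factor set).
#' @return A named numeric vector of class `cell_parameters` with attributes
#'   `region` and `remodeling`.
#' @export
#' @examples
#' p <- build_cell_parameters("MVR", "control")
#' p[["g_CaL"]] / default_cell_parameters()[["g_CaL"]] # 0.67
build_cell_parameters <- function(region = "RA", remodeling = "control",
                                  overrides = NULL) {
  region <- normalize_region(region)
  remodeling <- normalize_remodeling(remodeling)
  p <- default_cell_parameters()
  rp <- region_profiles()
  reg <- rp[rp$region == region, ]
  stopifnot(nrow(reg) == 1, all(unlist(reg[-1]) > 0))
  p["g_Na"] <- p["g_Na"] * reg$g_Na
  p["g_to"] <- p["g_to"] * reg$g_to
  p["g_CaL"] <- p["g_CaL"] * reg$g_CaL
  p["g_Kr"] <- p["g_Kr"] * reg$g_Kr
  p["g_Kur_sc"] <- p["g_Kur_sc"] * reg$g_Kur
  rm_ <- remodeling_profiles()
  rem <- rm_[rm_$remodeling == remodeling, ]
  stopifnot(nrow(rem) == 1, all(unlist(rem[-1]) > 0))
  p["g_CaL"] <- p["g_CaL"] * rem$I_CaL
  p["g_Kur_sc"] <- p["g_Kur_sc"] * rem$I_Kur
  p["g_to"] <- p["g_to"] * rem$I_to
  p["g_K1"] <- p["g_K1"] * rem$I_K1
  p["g_Ks"] <- p["g_Ks"] * rem$I_Ks
  p["g_Kr"] <- p["g_Kr"] * rem$I_Kr
  p["i_NaCa_max"] <- p["i_NaCa_max"] * rem$I_NaCa
  p["i_up_max"] <- p["i_up_max"] * rem$SERCA
  p["k_rel"] <- p["k_rel"] * rem$RyR
  # the base model defines the SR leak through the SERCA maximum
  # (leak = i_up_max * Ca_up / Ca_up_max), so the SERCA factor propagates
  # into the leak before the leak's own remodelling factor
  p["k_leak"] <- p["k_leak"] * rem$SERCA * rem$SR_leak
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% names(p)))
      stop("overrides must be named with valid parameter names")
    p[names(overrides)] <- overrides
  }
  if (any(p <= 0 & names(p) != "hbmdc"))
    stop("all conductances, rates and volumes must be strictly positive")
  attr(p, "region") <- region
  attr(p, "remodeling") <- remodeling
  class(p) <- c("cell_parameters", "numeric")
  p
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("<cell_parameters> region:", attr(x, "region") %||% "base",
      " remodeling:", attr(x, "remodeling") %||% "none", "\n")
  print(unclass(drop_attrs(x)))
  invisible(x)
}

drop_attrs <- function(x) {
  attributes(x) <- list(names = names(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
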
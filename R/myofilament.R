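#' Active strain from sarcomere length
#'
#' `gamma = (SL - SL0) / SL0`: negative during contraction, positive during
#' elongation, zero at the resting length.
#'
#' @param SL Sarcomere length (um), > 0.
#' @param SL0 Resting sarcomere length (um), > 0.
#' @return Active strain (dimensionless), vectorised.
#' @export
#' @examples
#' active_strain(1.71, 1.9) # -0.1
active_strain <- function(SL, SL0) {
  if (any(SL0 <= 0)) stop("SL0 must be strictly positive")
  if (any(SL <= 0)) stop("SL must be strictly positive")
  (SL - SL0) / SL0
}

#' Myofilament state derivatives and active force
#'
#' Evaluates the Rice crossbridge/regulatory-unit model at a given cytosolic
#' Ca2+ concentration: derivatives of the 11 myofilament states, the
#' normalised active force and the total troponin-bound Ca2+ flux.
#'
#' @param state Full cell state vector (only the myofilament entries are
#'   used, plus `SL`).
#' @param ca_uM Cytosolic Ca2+ (uM), >= 0.
#' @param params Parameter set.
#' @param mode `"isosarcometric"` (fixed SL) or `"shortening"` (SL dynamic
#'   against the internal viscoelastic load).
#' @return A list with `derivs` (named), `force` and `dTropTot` (uM/ms).
#' @export
myofilament_derivatives <- function(state, ca_uM,
                                    params = default_cell_parameters(),
                                    mode = c("isosarcometric",
                                             "shortening")) {
  mode <- match.arg(mode)
  if (ca_uM < 0) stop("calcium concentration must be non-negative")
  cpp_rice_derivs(as.numeric(state), as.numeric(params), ca_uM,
                  mech_mode = if (mode == "shortening") 1L else 0L,
                  sl_set = unname(params[["SL0"]]))
}

#' Myoplasmic Ca2+ balance of the coupled model
#'
#' The rate of change of cytosolic Ca2+ combining the sarcolemmal currents,
#' the SR uptake/leak/release fluxes and the troponin-bound Ca2+ flux from
#' the myofilament model (converted from uM/ms to mM/ms), all under
#' instantaneous calmodulin buffering.
#'
#' @param ca_i Cytosolic Ca2+ (mM).
#' @param currents Named list/vector with `I_CaL`, `I_bCa`, `I_pCa`,
#'   `I_NaCa` (pA/pF) and `I_up`, `I_leak`, `I_rel` (mM/ms).
#' @param dTropCa_dt Troponin-bound Ca2+ flux (uM/ms).
#' @param params Parameter set.
#' @return d\[Ca2+\]_i/dt in mM/ms.
#' @export
coupled_calcium_derivative <- function(ca_i, currents, dTropCa_dt,
                                       params = default_cell_parameters()) {
  vals <- unlist(currents)[c("I_CaL", "I_bCa", "I_pCa", "I_NaCa", "I_up",
                             "I_leak", "I_rel")]
  if (any(!is.finite(c(ca_i, vals, dTropCa_dt))))
    stop("all inputs must be finite")
  p <- as.list(params[c("Cm", "F", "V_i", "V_up", "V_rel", "CMDN_max",
                        "Km_CMDN")])
  b <- 1 / (1 + p$CMDN_max * p$Km_CMDN / (ca_i + p$Km_CMDN)^2)
  sarco <- -p$Cm * (vals[["I_CaL"]] + vals[["I_bCa"]] + vals[["I_pCa"]] -
                      2 * vals[["I_NaCa"]]) / (2 * p$V_i * p$F)
  sr <- (p$V_up * (vals[["I_leak"]] - vals[["I_up"]]) +
           vals[["I_rel"]] * p$V_rel) / p$V_i
  b * (sarco + sr - dTropCa_dt / 1000)
}

#' Steady-state force-calcium relation
#'
#' Integrates the myofilament model to steady state at each clamped Ca2+
#' level with the sarcomere held at a fixed length, returning the normalised
#' force-Ca curve (sigmoidal, monotone non-decreasing) together with a Hill
#' fit.
#'
#' @param params Parameter set.
#' @param ca_grid Ascending vector of Ca2+ levels (uM), > 0.
#' @param sl Clamped sarcomere length (um).
#' @param t_end Integration time used to reach steady state (ms).
#' @return A tibble of class `force_ca_curve` with columns `ca`, `force`,
#'   and attributes `ca50` and `hill` from the Hill fit.
#' @export
#' @examples
#' \donttest{
#' fc <- steady_state_force_calcium(ca_grid = c(0.5, 1, 2, 4))
#' attr(fc, "ca50")
#' }
steady_state_force_calcium <- function(params = default_cell_parameters(),
                                       ca_grid = 10^seq(-1, 1.3,
                                                        length.out = 25),
                                       sl = 2.2, t_end = 4000) {
  if (any(ca_grid <= 0) || is.unsorted(ca_grid))
    stop("ca_grid must be positive and ascending")
  force <- vapply(ca_grid, function(ca) {
    cpp_rice_clamp(as.numeric(params), ca, sl, t_end = t_end, dt = 0.05,
                   mech_mode = 0L)$force
  }, numeric(1))
  fmax <- max(force)
  out <- tibble::tibble(ca = ca_grid, force = force,
                        force_norm = force / fmax)
  fit <- hill_fit(out$ca, out$force_norm)
  attr(out, "ca50") <- fit$ca50
  attr(out, "hill") <- fit$n
  attr(out, "sl") <- sl
  class(out) <- c("force_ca_curve", class(out))
  out
}

# Hill fit of a normalised sigmoid on a log grid: F = ca^n/(ca50^n + ca^n)
hill_fit <- function(ca, f) {
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  keep <- f > 0.01 & f < 0.99
  if (sum(keep) < 3) keep <- rep(TRUE, length(f))
  y <- log(f[keep] / (1 - f[keep]))
  x <- log(ca[keep])
  co <- stats::coef(stats::lm(y ~ x))
  list(n = unname(co[2]), ca50 = exp(-unname(co[1]) / unname(co[2])))
}
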
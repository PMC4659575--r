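#' Initial state of the coupled cell model
#'
#' The CRN published resting state for the electrophysiology variables and a
#' near-relaxed myofilament configuration (non-permissive regulatory units,
#' sarcomere at its resting length). Pre-pacing relaxes any residual
#' transient.
#'
#' @param params Parameter set (used for the resting sarcomere length).
#' @return Named numeric state vector (membrane potential in mV, gates
#'   dimensionless, concentrations in mM, sarcomere length in um).
#' @export
cell_initial_state <- function(params = default_cell_parameters()) {
  s <- c(
    V = -81.18, m = 2.908e-3, h = 9.649e-1, j = 9.775e-1,
    oa = 3.043e-2, oi = 9.992e-1, ua = 4.966e-3, ui = 9.986e-1,
    xr = 3.296e-5, xs = 1.869e-2, d = 1.367e-4, f = 9.996e-1,
    fca = 7.755e-1, u = 0, v = 1, w = 9.992e-1,
    Na_i = 11.17, K_i = 139.0, Ca_i = 1.013e-4,
    Ca_up = 1.488, Ca_rel = 1.488,
    NNoXB = 0.99, PNoXB = 0.01, N = 0.98, XBprer = 0.005, XBpostr = 0.005,
    SL = unname(params[["SL0"]]), xXBprer = 0, xXBpostr = 7e-3,
    TRPNCaL = 0.015, TRPNCaH = 0.13, intf = 0
  )
  stopifnot(identical(names(s), as.character(cpp_state_names())))
  s
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != length(cpp_state_names()))
    stop("state must be a numeric vector of length ",
         length(cpp_state_names()))
  if (any(!is.finite(state))) stop("state contains non-finite values")
  gates <- state[2:16]
  if (any(gates < 0 | gates > 1)) stop("gating variables must lie in [0,1]")
  if (any(state[c("Na_i", "K_i", "Ca_i", "Ca_up", "Ca_rel")] <= 0))
    stop("ionic concentrations must be positive")
  invisible(state)
}

#' Transmembrane ionic currents and SR fluxes at a given state
#'
#' Evaluates every membrane current density (pA/pF) of the CRN model, the SR
#' uptake/release/leak fluxes (mM/ms), the total ionic current, the
#' normalised active force and the troponin-bound Ca2+ flux.
#'
#' @param state Named state vector (see [cell_initial_state()]).
#' @param params Parameter set from [build_cell_parameters()].
#' @return A one-row tibble with one column per current/flux.
#' @export
#' @examples
#' ionic_currents(cell_initial_state(), default_cell_parameters())
ionic_currents <- function(state, params = default_cell_parameters()) {
  validate_state(state)
  cur <- cpp_cell_currents(as.numeric(state), as.numeric(params))
  tibble::as_tibble(as.list(cur))
}

#' Advance the cell state by one time step
#'
#' Hodgkin-Huxley gates take the exact-exponential (Rush-Larsen) update at
#' frozen membrane potential; the junctional-SR Ca2+ compartment takes the
#' exponential update of its frozen-coefficient linear balance; the remaining
#' states are advanced explicitly.
#'
#' @inheritParams ionic_currents
#' @param dt Time step (ms), > 0.
#' @param n Number of steps to take.
#' @param i_stim Stimulus amplitude (pA/pF, positive depolarising).
#' @param mech_mode `"shortening"` (sarcomere free to shorten) or
#'   `"isosarcometric"` (fixed length).
#' @return The advanced named state vector.
#' @export
gate_step <- function(state, params, dt, n = 1L, i_stim = 0,
                      mech_mode = c("shortening", "isosarcometric")) {
  validate_state(state)
  if (dt <= 0) stop("dt must be positive")
  mode <- match.arg(mech_mode)
  res <- cpp_cell_run(as.numeric(state), as.numeric(params),
                      stim_times = if (i_stim != 0) 0 else numeric(0),
                      stim_dur = n * dt, stim_amp = i_stim,
                      t_end = n * dt, dt = dt, record_start = Inf,
                      record_dt = dt,
                      mech_mode = if (mode == "shortening") 1L else 0L,
                      stim_in_ki = FALSE, record_currents = FALSE,
                      sl_set = unname(params[["SL0"]]))
  setNames(res$final_state, names(state))
}
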
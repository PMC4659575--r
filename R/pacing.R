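#' Pacing protocol description
#'
#' S1-S2 pacing: a conditioning train of `s1_count` stimuli at `s1_freq`
#' (with the first `prepace_beats` of those treated as pre-pacing, i.e. not
#' recorded), optionally followed by a single premature S2 stimulus at
#' `s2_interval` after the last S1. Stimuli are rectangular current pulses;
#' with `stim_amp = "auto"` the amplitude is set to twice the diastolic
#' threshold found by bisection.
#'
#' @param s1_count Number of S1 beats (>= 1). The default protocol is 1000
#'   S1 stimuli at 1 Hz.
#' @param s1_freq S1 frequency (Hz), > 0.
#' @param s2_interval Coupling interval of the single S2 stimulus (ms), or
#'   `NA` for no S2.
#' @param stim_amp Stimulus amplitude in pA/pF (positive depolarising), or
#'   `"auto"`.
#' @param stim_dur Stimulus duration (ms).
#' @param record_beats Number of trailing beats to record in full.
#' @return A `pacing_protocol` list.
#' @export
pacing_protocol <- function(s1_count = 1000, s1_freq = 1, s2_interval = NA,
                            stim_amp = "auto", stim_dur = 2,
                            record_beats = 2) {
  stopifnot(s1_count >= 1, s1_freq > 0, stim_dur > 0, record_beats >= 1)
  structure(list(s1_count = as.integer(s1_count), s1_freq = s1_freq,
                 s2_interval = s2_interval, stim_amp = stim_amp,
                 stim_dur = stim_dur,
                 record_beats = min(record_beats, s1_count)),
            class = "pacing_protocol")
}

#' Diastolic stimulus threshold by bisection
#'
#' Finds the smallest rectangular-pulse amplitude that elicits an action
#' potential (overshoot above 0 mV within 50 ms) from the resting state.
#'
#' @param params Parameter set.
#' @param stim_dur Pulse duration (ms).
#' @param lo,hi Initial bisection bracket (pA/pF).
#' @param tol Bisection tolerance (pA/pF).
#' @param state Starting state; defaults to the model resting state.
#' @return Threshold amplitude (pA/pF).
#' @export
calibrate_stimulus <- function(params, stim_dur = 2, lo = 0.5, hi = 80,
                               tol = 0.25, state = cell_initial_state(params)) {
  fires <- function(amp) {
    res <- cpp_cell_run(as.numeric(state), as.numeric(params),
                        stim_times = 5, stim_dur = stim_dur, stim_amp = amp,
                        t_end = 55, dt = 0.02, record_start = 0,
                        record_dt = 0.5, mech_mode = 0L, stim_in_ki = FALSE,
                        record_currents = FALSE)
    max(res$trace[, "V"]) > 0
  }
  if (!fires(hi)) stop("no action potential elicited even at amplitude ", hi)
  if (fires(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Run an S1-S2 pacing protocol on a regional cell model
#'
#' Builds the cell for the requested region and remodelling condition,
#' applies the pacing protocol and returns the recorded trailing beats as a
#' tidy trace together with per-beat biomarkers.
#'
#' @param region Region identifier (see [region_profiles()]).
#' @param remodeling `"control"` or `"af"`.
#' @param protocol A [pacing_protocol()].
#' @param dt Integration step (ms).
#' @param params Optional pre-built parameter set (overrides
#'   region/remodeling).
#' @param state Optional starting state (e.g. a pre-paced snapshot).
#' @param mech_mode `"shortening"` or `"isosarcometric"`.
#' @param record_dt Trace sampling interval (ms).
#' @param record_currents Record current densities along with states.
#' @return A `pacing_result` with elements `trace` (tibble), `biomarkers`
#'   (per recorded beat, see [compute_biomarkers()]), `final_state`,
#'   `gate_range`, `protocol`, `region`, `remodeling`, `stim_amp`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pacing("RA", "control", pacing_protocol(s1_count = 5))
#' glance(res)
#' }
run_pacing <- function(region = "RA", remodeling = "control",
                       protocol = pacing_protocol(), dt = 0.02,
                       params = NULL, state = NULL,
                       mech_mode = c("shortening", "isosarcometric"),
                       record_dt = 0.1, record_currents = TRUE) {
  mode <- match.arg(mech_mode)
  if (is.null(params)) params <- build_cell_parameters(region, remodeling)
  region <- attr(params, "region") %||% region
  remodeling <- attr(params, "remodeling") %||% remodeling
  if (is.null(state)) state <- cell_initial_state(params)
  validate_state(state)

  cl <- 1000 / protocol$s1_freq
  stim_times <- (seq_len(protocol$s1_count) - 1) * cl + 10
  if (!is.na(protocol$s2_interval))
    stim_times <- c(stim_times, stim_times[length(stim_times)] +
                      protocol$s2_interval)
  t_end <- max(stim_times) + cl
  amp <- protocol$stim_amp
  if (identical(amp, "auto"))
    amp <- 2 * calibrate_stimulus(params, protocol$stim_dur, state = state)
  record_start <- stim_times[max(1, protocol$s1_count -
                                   protocol$record_beats + 1)] - 10

  res <- cpp_cell_run(as.numeric(state), as.numeric(params),
                      stim_times = stim_times, stim_dur = protocol$stim_dur,
                      stim_amp = amp, t_end = t_end, dt = dt,
                      record_start = record_start, record_dt = record_dt,
                      mech_mode = if (mode == "shortening") 1L else 0L,
                      stim_in_ki = TRUE, record_currents = record_currents,
                      sl_set = unname(params[["SL0"]]))
  trace <- tibble::as_tibble(as.data.frame(res$trace))
  trace$gamma <- active_strain(trace$SL, unname(params[["SL0"]]))

  recorded_stims <- stim_times[stim_times >= record_start]
  bm <- compute_biomarkers(trace, stim_times = recorded_stims,
                           stim_dur = protocol$stim_dur,
                           sl0 = unname(params[["SL0"]]))
  out <- structure(list(trace = trace, biomarkers = bm,
                        final_state = res$final_state,
                        gate_range = list(min = res$gate_min,
                                          max = res$gate_max,
                                          conc_min = res$conc_min),
                        protocol = protocol, region = region,
                        remodeling = remodeling, stim_amp = amp, dt = dt),
                   class = "pacing_result")
  out
}

#' @export
print.pacing_result <- function(x, ...) {
  cat("<pacing_result>", x$region, "/", x$remodeling, "-",
      x$protocol$s1_count, "S1 beats at", x$protocol$s1_freq, "Hz\n")
  cat("stimulus:", format(x$stim_amp, digits = 3), "pA/pF x",
      x$protocol$stim_dur, "ms\n")
  print(x$biomarkers)
  invisible(x)
}

#' @rdname run_pacing
#' @param x A `pacing_result`.
#' @param ... Unused.
#' @export
tidy.pacing_result <- function(x, ...) x$biomarkers

#' @rdname run_pacing
#' @export
glance.pacing_result <- function(x, ...) {
  last <- x$biomarkers[nrow(x$biomarkers), ]
  dplyr::mutate(last, region = x$region, remodeling = x$remodeling,
                .before = 1)
}
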
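#' Per-beat electromechanical biomarkers from a trace
#'
#' For each beat (delimited by the stimulus onsets, or the whole trace when
#' none are given) measures: APD90 from the instant of maximum upstroke
#' velocity to 90% repolarisation of the amplitude `V_max - V_dia` (with
#' `V_dia` sampled immediately before the stimulus), diastolic and systolic
#' cytosolic Ca2+, sarcomere shortening as a percentage of the resting
#' length, the peak active force and the pre-stimulus (diastolic)
#' volume-weighted SR Ca2+ content. Beats that fail to repolarise to the 90%
#' level before the next stimulus are flagged (`repolarized = FALSE`) with
#' `apd90 = NA` rather than silently measured.
#'
#' @param trace A tibble/data frame with columns `t`, `V`, and optionally
#'   `Ca_i`, `SL`, `F_active`, `Ca_up`, `Ca_rel`.
#' @param stim_times Stimulus onset times (ms) within the trace; optional.
#' @param stim_dur Stimulus duration (ms), used to skip the stimulus
#'   artefact when locating the upstroke.
#' @param sl0 Resting sarcomere length (um) for the shortening percentage.
#' @param v_up,v_rel SR compartment volumes (um^3) for the content measure.
#' @return A tibble with one row per beat.
#' @export
#' @examples
#' tr <- tibble::tibble(t = seq(0, 250, 0.5),
#'                      V = c(-80, pmax(20 - 0.5 * seq(0.5, 250, 0.5), -80)))
#' compute_biomarkers(tr)$apd90
compute_biomarkers <- function(trace, stim_times = NULL, stim_dur = 2,
                               sl0 = 1.9, v_up = 1109.52, v_rel = 96.48) {
  trace <- as.data.frame(trace)
  if (!all(c("t", "V") %in% names(trace)))
    stop("trace must contain columns 't' and 'V'")
  if (nrow(trace) < 10) stop("trace too short to contain a full beat")
  if (is.null(stim_times)) stim_times <- trace$t[1]
  stim_times <- stim_times[stim_times >= trace$t[1] - 1e-9 &
                             stim_times < trace$t[nrow(trace)]]
  if (length(stim_times) == 0) stop("no stimulus falls inside the trace")
  bounds <- c(stim_times, trace$t[nrow(trace)] + 1e-9)

  one_beat <- function(b) {
    t0 <- bounds[b]; t1 <- bounds[b + 1]
    pre <- trace[trace$t <= t0 + 1e-9, ]
    v_dia <- if (nrow(pre)) pre$V[nrow(pre)] else trace$V[1]
    seg <- trace[trace$t >= t0 - 1e-9 & trace$t < t1, ]
    if (nrow(seg) < 5) return(NULL)
    v_max <- max(seg$V)
    amp <- v_max - v_dia
    if (!is.finite(amp) || amp < 15)
      stop("no action potential detected (amplitude ",
           format(amp, digits = 3), " mV)", call. = FALSE)
    dv <- diff(seg$V) / diff(seg$t)
    # upstroke: fastest depolarisation after the stimulus onset
    up_i <- which.max(dv)
    t_up <- seg$t[up_i]
    v90 <- v_max - 0.9 * amp
    after_peak <- seg[seg$t >= seg$t[which.max(seg$V)], ]
    below <- which(after_peak$V <= v90)
    if (length(below) == 0) {
      apd90 <- NA_real_; repol <- FALSE
    } else {
      i <- below[1]
      if (i == 1) {
        t90 <- after_peak$t[1]
      } else {
        t90 <- approx(after_peak$V[c(i - 1, i)], after_peak$t[c(i - 1, i)],
                      xout = v90)$y
      }
      apd90 <- t90 - t_up; repol <- TRUE
    }
    out <- tibble::tibble(
      beat = b, t_stim = t0, v_rest = v_dia, v_max = v_max,
      dvdt_max = max(dv), apd90 = apd90, repolarized = repol
    )
    if ("Ca_i" %in% names(seg)) {
      ca_dia <- if (nrow(pre)) pre$Ca_i[nrow(pre)] else seg$Ca_i[1]
      out$ca_dia <- ca_dia
      out$ca_sys <- max(seg$Ca_i)
      out$ca_amp <- out$ca_sys - ca_dia
    }
    if ("SL" %in% names(seg)) {
      out$sl_min <- min(seg$SL)
      out$sl_shortening_pct <- 100 * (sl0 - out$sl_min) / sl0
    }
    if ("F_active" %in% names(seg)) out$force_peak <- max(seg$F_active)
    if (all(c("Ca_up", "Ca_rel") %in% names(seg))) {
      pre_row <- if (nrow(pre)) pre[nrow(pre), ] else seg[1, ]
      out$sr_content_dia <- pre_row$Ca_up * v_up + pre_row$Ca_rel * v_rel
    }
    out
  }
  res <- dplyr::bind_rows(lapply(seq_along(stim_times), one_beat))
  if (nrow(res) == 0) stop("no complete beat found in trace")
  res
}

#' Signed percentage change, reported as a reduction
#'
#' `100 * (control - test) / control`: positive values mean the test
#' condition is reduced relative to control.
#'
#' @param control_value,test_value Numeric scalars or vectors.
#' @return Percentage reduction (negative for an increase).
#' @export
#' @examples
#' percent_change(274, 188) # ~31
percent_change <- function(control_value, test_value) {
  if (any(control_value == 0)) stop("control value must be non-zero")
  100 * (control_value - test_value) / control_value
}

#' Biomarker sweep over the regional cell family
#'
#' Runs the pacing protocol for every region under each requested
#' remodelling condition and tabulates the final-beat biomarkers. Active
#' force is additionally normalised to the control baseline-RA peak. When
#' both conditions are present the control-to-AF percentage changes are
#' appended. Per-region failures are recorded in the `error` column and the
#' sweep continues.
#'
#' @param remodeling Character vector of conditions to run.
#' @param protocol A [pacing_protocol()].
#' @param regions Regions to include (default: all profiles).
#' @param dt Integration step (ms).
#' @param ... Passed to [run_pacing()].
#' @return A tibble of class `region_sweep` with one row per region x
#'   condition plus attached wide summary (see [sweep_table()]).
#' @export
region_sweep <- function(remodeling = c("control", "af"),
                         protocol = pacing_protocol(),
                         regions = region_profiles()$region, dt = 0.02,
                         ...) {
  remodeling <- vapply(remodeling, normalize_remodeling, character(1))
  rows <- list()
  for (rem in remodeling) {
    for (reg in regions) {
      row <- tryCatch({
        res <- run_pacing(reg, rem, protocol, dt = dt, ...)
        dplyr::mutate(glance(res), error = NA_character_)
      }, error = function(e) {
        reg_id <- tryCatch(normalize_region(reg),
                           error = function(...) as.character(reg))
        tibble::tibble(region = reg_id, remodeling = rem,
                       error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  if ("force_peak" %in% names(out)) {
    ra_ctl <- out$force_peak[out$region == "RA" &
                               out$remodeling == "control"]
    if (length(ra_ctl) == 1 && is.finite(ra_ctl) && ra_ctl > 0)
      out$force_norm <- out$force_peak / ra_ctl
  }
  class(out) <- c("region_sweep", class(out))
  out
}

#' Wide per-region summary of a sweep (control vs AF)
#'
#' Reshapes a [region_sweep()] result into one row per region with control
#' and AF columns and the control-to-AF percentage changes in APD90,
#' systolic Ca2+ and peak active force.
#'
#' @param sweep A `region_sweep` tibble containing both conditions.
#' @return A tibble with one row per region.
#' @export
sweep_table <- function(sweep) {
  need <- c("region", "remodeling", "apd90", "ca_sys", "force_peak")
  stopifnot(all(need %in% names(sweep)))
  wide <- tidyr::pivot_wider(
    dplyr::select(dplyr::filter(sweep, is.na(.data$error)),
                  dplyr::all_of(c(need, "ca_dia"))),
    names_from = "remodeling",
    values_from = c("apd90", "ca_sys", "ca_dia", "force_peak"))
  if (all(c("apd90_control", "apd90_af") %in% names(wide))) {
    wide <- dplyr::mutate(
      wide,
      apd90_change_pct = percent_change(.data$apd90_control, .data$apd90_af),
      ca_sys_change_pct = percent_change(.data$ca_sys_control,
                                         .data$ca_sys_af),
      ca_dia_change_pct = percent_change(.data$ca_dia_control,
                                         .data$ca_dia_af),
      force_change_pct = percent_change(.data$force_peak_control,
                                        .data$force_peak_af))
  }
  wide
}

#' @export
tidy.region_sweep <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.region_sweep <- function(x, ...) sweep_table(x)
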
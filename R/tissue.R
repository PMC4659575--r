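#' 1D cable fixture
#'
#' Builds a regular 1D lattice of coupled cells with a per-segment regional
#' assignment (e.g. a composite RA|PV cable).
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param dx Node spacing (mm), > 0.
#' @param region_map Either a single region identifier for the whole cable
#'   or a character vector of length `n_nodes` assigning one per node.
#' @param remodeling Remodelling condition applied to every segment.
#' @param d_l Longitudinal diffusion coefficient (mm^2/ms).
#' @return A `tissue_grid`.
#' @export
#' @examples
#' cab <- make_cable(100, region_map = "RA")
make_cable <- function(n_nodes, dx = 0.25, region_map = "RA",
                       remodeling = "control", d_l = 1.26) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  if (dx <= 0) stop("dx must be positive")
  if (length(region_map) == 1) region_map <- rep(region_map, n_nodes)
  if (length(region_map) != n_nodes)
    stop("region_map must have 1 or n_nodes entries")
  regions <- vapply(region_map, normalize_region, character(1))
  uniq <- unique(regions)
  sets <- lapply(uniq, build_cell_parameters, remodeling = remodeling)
  structure(list(nx = as.integer(n_nodes), ny = 1L, dx = dx,
                 theta = rep(0, n_nodes), d_l = d_l, d_t = d_l,
                 sets = sets, set_names = uniq,
                 set_idx = match(regions, uniq),
                 C = NULL, states = NULL),
            class = "tissue_grid")
}

#' 2D fibred sheet fixture
#'
#' Regular 2D lattice with a uniform (or jittered) fibre field at a given
#' angle; the diffusion tensor is assembled from the longitudinal and
#' transverse conductivities and the fibre direction.
#'
#' @param nx,ny Lattice dimensions (>= 2).
#' @param dx Node spacing (mm).
#' @param fibre_angle Fibre angle in degrees from the x axis.
#' @param region,remodeling Cell model assignment for the whole sheet.
#' @param d_l,d_t Longitudinal/transverse diffusion coefficients
#'   (mm^2/ms); the defaults are the printed atrial values (3:1 ratio).
#' @param angle_jitter_sd Standard deviation (degrees) of per-node Gaussian
#'   jitter added to the fibre angle (uses the current RNG state).
#' @return A `tissue_grid`.
#' @export
#' @examples
#' sh <- make_sheet(20, 20, fibre_angle = 0)
make_sheet <- function(nx, ny, dx = 0.25, fibre_angle = 0, region = "RA",
                       remodeling = "control", d_l = 1.26, d_t = 0.42,
                       angle_jitter_sd = 0) {
  if (nx < 2 || ny < 2) stop("nx and ny must be at least 2")
  if (dx <= 0) stop("dx must be positive")
  n <- nx * ny
  theta <- rep(fibre_angle * pi / 180, n)
  if (angle_jitter_sd > 0)
    theta <- theta + stats::rnorm(n, 0, angle_jitter_sd * pi / 180)
  p <- build_cell_parameters(region, remodeling)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 theta = theta, d_l = d_l, d_t = d_t,
                 sets = list(p), set_names = normalize_region(region),
                 set_idx = rep(1L, n), C = NULL, states = NULL),
            class = "tissue_grid")
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("<tissue_grid>", x$nx, "x", x$ny, "nodes, dx =", x$dx, "mm,",
      "cell sets:", paste(x$set_names, collapse = ", "), "\n")
  invisible(x)
}

#' Diffusion tensor field of a grid
#'
#' `D = R(theta) diag(d_l, d_t) R(theta)^T` per node.
#'
#' @param grid A `tissue_grid`.
#' @return A tibble with columns `Dxx`, `Dxy`, `Dyy` (mm^2/ms).
#' @export
diffusion_tensor <- function(grid) {
  ct <- cos(grid$theta); st <- sin(grid$theta)
  tibble::tibble(
    Dxx = grid$d_l * ct^2 + grid$d_t * st^2,
    Dxy = (grid$d_l - grid$d_t) * ct * st,
    Dyy = grid$d_l * st^2 + grid$d_t * ct^2)
}

# Effective tensor M = D C^-1 (symmetrised; errors if the product is
# non-symmetric / non-SPD beyond tolerance).
effective_tensor <- function(grid) {
  D <- diffusion_tensor(grid)
  if (is.null(grid$C)) {
    return(list(Mxx = D$Dxx, Mxy = D$Dxy, Myy = D$Dyy))
  }
  C <- grid$C
  if (!is.matrix(C) || ncol(C) != 3 || nrow(C) != length(grid$theta))
    stop("deformation field C must have one row per node ",
         "(projection between incompatible grids)")
  det <- C[, 1] * C[, 3] - C[, 2]^2
  if (any(det <= 0) || any(C[, 1] <= 0) || any(C[, 3] <= 0))
    stop("deformation tensor C must be symmetric positive-definite")
  ixx <- C[, 3] / det; ixy <- -C[, 2] / det; iyy <- C[, 1] / det
  Mxx <- D$Dxx * ixx + D$Dxy * ixy
  Mxy <- D$Dxx * ixy + D$Dxy * iyy
  Myx <- D$Dxy * ixx + D$Dyy * ixy
  Myy <- D$Dxy * ixy + D$Dyy * iyy
  scale <- max(abs(c(Mxx, Myy)))
  if (max(abs(Mxy - Myx)) > 1e-6 * scale)
    stop("effective tensor D C^-1 is not symmetric: ",
         "C must share principal axes with D")
  list(Mxx = Mxx, Mxy = (Mxy + Myx) / 2, Myy = Myy)
}

#' Set or reset the deformation field of a grid
#'
#' Either a prescribed constant right Cauchy-Green tensor (components
#' `cxx`, `cxy`, `cyy`) applied to every node, or `NULL` to reset to the
#' identity (undeformed tissue).
#'
#' @param grid A `tissue_grid`.
#' @param cxx,cxy,cyy Tensor components (recycled over nodes).
#' @return The modified grid.
#' @export
set_deformation <- function(grid, cxx = 1, cxy = 0, cyy = 1) {
  n <- grid$nx * grid$ny
  grid$C <- cbind(rep_len(cxx, n), rep_len(cxy, n), rep_len(cyy, n))
  grid
}

# Kinematic fibre-shortening deformation: F0 = I + gamma f x f with
# incompressible transverse compensation; C has eigenvalues ((1+gamma)^2,
# 1/(1+gamma)) along (f, f_perp).
kinematic_C <- function(grid, gamma) {
  lam2_f <- (1 + gamma)^2
  lam2_t <- 1 / (1 + gamma)
  ct <- cos(grid$theta); st <- sin(grid$theta)
  cbind(lam2_f * ct^2 + lam2_t * st^2,
        (lam2_f - lam2_t) * ct * st,
        lam2_f * st^2 + lam2_t * ct^2)
}

#' Initialise tissue states from pre-paced single cells
#'
#' Runs each distinct cell set of the grid in isolation for `prepace_beats`
#' beats at `freq` Hz and copies the resulting steady state to every node of
#' that set.
#'
#' @param grid A `tissue_grid`.
#' @param prepace_beats Pre-pacing beat count (0 = resting state).
#' @param freq Pacing frequency (Hz).
#' @param dt Integration step (ms).
#' @return The grid with a `states` matrix attached.
#' @export
prepace_grid <- function(grid, prepace_beats = 200, freq = 1, dt = 0.02) {
  n <- grid$nx * grid$ny
  states <- matrix(0, n, length(cpp_state_names()))
  for (s in seq_along(grid$sets)) {
    p <- grid$sets[[s]]
    st <- cell_initial_state(p)
    if (prepace_beats > 0) {
      res <- run_pacing(params = p,
                        protocol = pacing_protocol(s1_count = prepace_beats,
                                                   s1_freq = freq,
                                                   record_beats = 1),
                        dt = dt, record_currents = FALSE)
      st <- res$final_state
    }
    states[grid$set_idx == s, ] <- matrix(st, sum(grid$set_idx == s),
                                          length(st), byrow = TRUE)
  }
  colnames(states) <- as.character(cpp_state_names())
  grid$states <- states
  grid
}

#' Stimulus event for tissue simulations
#'
#' @param nodes Integer vector of 1-based node indices.
#' @param onset Onset time (ms).
#' @param duration Duration (ms), > 0.
#' @param amplitude Amplitude (pA/pF, positive depolarising).
#' @return A `stimulus_event`.
#' @export
stimulus_event <- function(nodes, onset, duration = 2, amplitude = 40) {
  if (duration <= 0) stop("stimulus duration must be positive")
  if (length(nodes) == 0) stop("stimulus needs at least one node")
  structure(list(nodes = as.integer(nodes), onset = onset,
                 duration = duration, amplitude = amplitude),
            class = "stimulus_event")
}

#' Node indices of simple stimulus geometries
#'
#' `edge`: the first `width` columns (a plane-wave source); `quadrant`: the
#' lower-left quarter of the sheet (cross-field S2 geometry); `all`: every
#' node.
#'
#' @param grid A `tissue_grid`.
#' @param what `"edge"`, `"quadrant"` or `"all"`.
#' @param width Number of columns for `"edge"`.
#' @return Integer node indices (1-based).
#' @export
grid_nodes <- function(grid, what = c("edge", "quadrant", "all"),
                       width = 3) {
  what <- match.arg(what)
  ix <- rep(seq_len(grid$nx), grid$ny)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  which(switch(what,
               edge = ix <= width,
               quadrant = ix <= grid$nx / 2 & iy <= grid$ny / 2,
               all = rep(TRUE, grid$nx * grid$ny)))
}

#' Run the monodomain model on a grid
#'
#' Strang-split integration (half reaction, Crank-Nicolson diffusion of
#' `div(D C^-1 grad V)` with no-flux boundaries, half reaction). With
#' `coupled = TRUE` the deformation field is refreshed every `dt_mech` from
#' the local sarcomere shortening (kinematic active-strain surrogate), which
#' in turn rescales the conductivity tensor — the staggered electromechanics
#' exchange.
#'
#' @param grid A `tissue_grid`, pre-paced or not (resting cells are used
#'   when `states` is missing).
#' @param t_end Simulation length (ms).
#' @param stimuli List of [stimulus_event()]s.
#' @param dt Diffusion/splitting step (ms).
#' @param ode_dt Reaction sub-step cap (ms).
#' @param probes Node indices to record V from, every `record_dt` ms.
#' @param record_dt Probe sampling interval (ms).
#' @param mech_mode `"isosarcometric"` or `"shortening"`.
#' @param coupled Exchange deformation with the electrophysiology.
#' @param dt_mech Mechanics exchange interval (ms).
#' @param t0 Global time offset of this run (ms).
#' @return A `tissue_result`: the updated grid (with final states), probe
#'   traces (tibble), per-node activation counts/times, time of maximal
#'   upstroke per node, and the mean fibre shortening history if coupled.
#' @export
simulate_tissue <- function(grid, t_end, stimuli = list(), dt = 0.02,
                            ode_dt = 0.01, probes = integer(0),
                            record_dt = 0.5,
                            mech_mode = c("isosarcometric", "shortening"),
                            coupled = FALSE, dt_mech = 1, t0 = 0) {
  mech_mode <- match.arg(mech_mode)
  if (t_end <= 0) stop("t_end must be positive")
  if (inherits(stimuli, "stimulus_event")) stimuli <- list(stimuli)
  if (is.null(grid$states)) grid <- prepace_grid(grid, prepace_beats = 0)
  n <- grid$nx * grid$ny
  pm <- vapply(grid$sets, as.numeric,
               numeric(length(cpp_param_names())))
  pm <- matrix(pm, nrow = length(cpp_param_names()))
  ev_nodes <- lapply(stimuli, function(e) e$nodes - 1L)
  ev_t <- vapply(stimuli, `[[`, numeric(1), "onset")
  ev_d <- vapply(stimuli, `[[`, numeric(1), "duration")
  ev_a <- vapply(stimuli, `[[`, numeric(1), "amplitude")
  mm <- if (mech_mode == "shortening") 1L else 0L

  run_chunk <- function(states, M, tc, len) {
    cpp_tissue_run(states, pm, grid$set_idx - 1L, M$Mxx,
                   if (length(M$Mxy) == 1) rep(M$Mxy, n) else M$Mxy,
                   if (length(M$Myy) == 1) rep(M$Myy, n) else M$Myy,
                   grid$nx, grid$ny, grid$dx, dt, tc, len,
                   ev_nodes, ev_t, ev_d, ev_a, probes - 1L, record_dt,
                   mm, ode_dt)
  }

  states <- grid$states
  gamma_hist <- NULL
  if (!coupled) {
    res <- run_chunk(states, effective_tensor(grid), t0, t_end)
  } else {
    tc <- t0
    agg <- NULL
    sl0 <- vapply(grid$sets, function(p) unname(p[["SL0"]]), numeric(1))
    gh <- list()
    while (tc < t0 + t_end - 1e-9) {
      len <- min(dt_mech, t0 + t_end - tc)
      gamma <- active_strain(states[, "SL"], sl0[grid$set_idx])
      grid$C <- kinematic_C(grid, gamma)
      gh[[length(gh) + 1]] <- c(t = tc, gamma_mean = mean(gamma))
      res <- run_chunk(states, effective_tensor(grid), tc, len)
      states <- res$states
      colnames(states) <- colnames(grid$states)
      agg <- merge_tissue_results(agg, res)
      tc <- tc + len
    }
    res <- agg
    gamma_hist <- tibble::as_tibble(do.call(rbind, gh))
  }
  states <- res$states
  colnames(states) <- as.character(cpp_state_names())
  grid$states <- states

  ptr <- res$probe_trace
  trace <- if (length(probes) && nrow(ptr) > 0) {
    colnames(ptr) <- c("t", paste0("node", probes))
    tidyr::pivot_longer(tibble::as_tibble(as.data.frame(ptr)), -"t",
                        names_to = "probe", values_to = "V")
  } else tibble::tibble(t = numeric(0), probe = character(0), V = numeric(0))

  structure(list(grid = grid, trace = trace,
                 act_count = res$act_count, first_act = res$first_act,
                 last_act = res$last_act, t_max_dvdt = res$t_max_dvdt,
                 max_dvdt = res$max_dvdt,
                 t_last_activation = res$t_last_activation,
                 gamma_hist = gamma_hist, t0 = t0, t_end = t_end),
            class = "tissue_result")
}

merge_tissue_results <- function(a, b) {
  if (is.null(a)) return(b)
  b$act_count <- a$act_count + b$act_count
  b$first_act <- ifelse(is.na(a$first_act), b$first_act, a$first_act)
  b$last_act <- ifelse(is.na(b$last_act), a$last_act, b$last_act)
  keep_b <- !is.na(b$max_dvdt) & (is.na(a$max_dvdt) |
                                    b$max_dvdt > a$max_dvdt)
  b$t_max_dvdt <- ifelse(keep_b, b$t_max_dvdt, a$t_max_dvdt)
  b$max_dvdt <- pmax(a$max_dvdt, b$max_dvdt, na.rm = TRUE)
  if (is.na(b$t_last_activation))
    b$t_last_activation <- a$t_last_activation
  if (nrow(a$probe_trace) > 0)
    b$probe_trace <- rbind(a$probe_trace, b$probe_trace)
  b
}

#' @export
print.tissue_result <- function(x, ...) {
  cat("<tissue_result>", x$grid$nx, "x", x$grid$ny, "for", x$t_end, "ms;",
      sum(x$act_count > 0), "nodes activated\n")
  invisible(x)
}

#' Planar-wave conduction velocity
#'
#' Stimulates one edge of the grid, propagates a planar wave along the given
#' axis and measures CV from the activation-time (maximum upstroke rate)
#' difference between two probe nodes placed at 30% and 70% of the domain
#' length on the centre line (>= 10 nodes apart, away from the boundaries).
#'
#' @param grid A `tissue_grid` (pre-paced states recommended).
#' @param axis `"x"` or `"y"`.
#' @param t_end Simulation window (ms).
#' @param dt,ode_dt Time steps (ms).
#' @param stim_amp Stimulus amplitude (pA/pF).
#' @return A one-row tibble with `cv` (mm/ms), probe metadata and the run.
#' @export
measure_cv <- function(grid, axis = c("x", "y"), t_end = 60, dt = 0.02,
                       ode_dt = 0.01, stim_amp = 40) {
  axis <- match.arg(axis)
  nx <- grid$nx; ny <- grid$ny
  if (axis == "y" && ny < 10) stop("grid too small for y-axis CV")
  along <- if (axis == "x") nx else ny
  i1 <- max(2, round(0.3 * along)); i2 <- min(along - 1, round(0.7 * along))
  if (i2 - i1 < 10) stop("grid too small: probes must be >= 10 nodes apart")
  mid_row <- max(1, round(ny / 2)); mid_col <- max(1, round(nx / 2))
  node <- function(ix, iy) (iy - 1) * nx + ix
  w <- max(3, ceiling(2 / grid$dx))  # ~2 mm stimulated strip
  if (axis == "x") {
    stim_nodes <- node(rep(seq_len(w), ny), rep(seq_len(ny), each = w))
    p1 <- node(i1, mid_row); p2 <- node(i2, mid_row)
  } else {
    stim_nodes <- node(rep(seq_len(nx), w), rep(seq_len(w), each = nx))
    p1 <- node(mid_col, i1); p2 <- node(mid_col, i2)
  }
  res <- simulate_tissue(grid, t_end,
                         stimulus_event(stim_nodes, onset = 1,
                                        amplitude = stim_amp),
                         dt = dt, ode_dt = ode_dt)
  t1 <- res$t_max_dvdt[p1]; t2 <- res$t_max_dvdt[p2]
  if (res$act_count[p1] == 0 || res$act_count[p2] == 0 ||
      !is.finite(t1) || !is.finite(t2) || t2 <= t1)
    stop("no activation recorded at the probe nodes (wave failed to ",
         "propagate)")
  cv <- (i2 - i1) * grid$dx / (t2 - t1)
  tibble::tibble(axis = axis, cv = cv, t1 = t1, t2 = t2,
                 distance = (i2 - i1) * grid$dx)
}

#' Cross-field S1-S2 re-entry induction on a 2D sheet
#'
#' S1 plane wave from one edge at t = 0, then a premature S2 over one
#' quadrant at the given delay (the cross-field protocol). Reports whether
#' re-entrant activity is sustained (last activation at least
#' `sustained_ms` after S2 and outlasting three S1 cycle lengths), per-node
#' activation counts and a dominant cycle length estimate at a probe.
#'
#' @param grid A pre-paced 2D `tissue_grid`.
#' @param s2_delay S2 onset relative to S1 (ms).
#' @param t_after Observation window after S2 (ms).
#' @param s1_cycle Nominal S1 cycle length (ms) for the outlasting check.
#' @param sustained_ms Sustained-activity threshold after S2 (ms).
#' @param dt,ode_dt Time steps (ms).
#' @param stim_amp Stimulus amplitude (pA/pF).
#' @return A `reentry_report` (one-row tibble plus attributes `act_count`,
#'   `probe_trace`).
#' @export
induce_reentry <- function(grid, s2_delay = 250, t_after = 1200,
                           s1_cycle = 1000, sustained_ms = 1000,
                           dt = 0.05, ode_dt = 0.0125, stim_amp = 40) {
  if (grid$ny < 2) stop("re-entry induction needs a 2D grid")
  s1 <- stimulus_event(grid_nodes(grid, "edge"), onset = 1,
                       amplitude = stim_amp)
  s2 <- stimulus_event(grid_nodes(grid, "quadrant"), onset = 1 + s2_delay,
                       duration = 5, amplitude = stim_amp)
  probe <- (round(grid$ny * 0.75) - 1) * grid$nx + round(grid$nx * 0.75)
  res <- simulate_tissue(grid, t_end = 1 + s2_delay + t_after,
                         stimuli = list(s1, s2), dt = dt, ode_dt = ode_dt,
                         probes = probe, record_dt = 1)
  t_s2 <- 1 + s2_delay
  t_last <- res$t_last_activation
  dur <- if (is.na(t_last)) 0 else max(0, t_last - t_s2)
  s2_captured <- any(res$act_count > 1)
  # dominant cycle length from probe activations
  pv <- res$trace$V
  up <- which(pv[-1] >= -40 & pv[-length(pv)] < -40)
  cyc <- if (length(up) >= 3) stats::median(diff(res$trace$t[up])) else NA
  out <- tibble::tibble(s2_delay = s2_delay, s2_captured = s2_captured,
                        activity_after_s2 = dur,
                        sustained = dur >= sustained_ms,
                        outlasts_3_cycles = dur >= 3 * s1_cycle,
                        dominant_cycle = cyc,
                        max_act_count = max(res$act_count))
  attr(out, "act_count") <- matrix(res$act_count, grid$nx, grid$ny)
  attr(out, "result") <- res
  class(out) <- c("reentry_report", class(out))
  out
}
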
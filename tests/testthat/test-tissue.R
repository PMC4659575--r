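# Tissue tests use short cables/sheets; CV checks run on resting cells
# (conduction is set by the upstroke, not pacing history).

test_that("uniform resting tissue evolves like a single cell (no-flux)", {
  cab <- make_cable(40, dx = 0.25)
  res <- simulate_tissue(cab, t_end = 50, probes = c(5, 20, 35),
                         record_dt = 1)
  # no stimulus: V stays uniform and matches the isolated cell
  v <- res$grid$states[, "V"]
  expect_lt(diff(range(v)), 1e-6)
  single <- gate_step(cell_initial_state(default_cell_parameters()),
                      default_cell_parameters(), dt = 0.02, n = 2500L)
  expect_equal(unname(v[1]), unname(single[["V"]]), tolerance = 1e-3)
})

test_that("deformation-aware step with C = I equals the standard
           monodomain solver", {
  cab <- make_cable(60, dx = 0.25)
  stim <- stimulus_event(1:8, onset = 1, amplitude = 40)
  res_plain <- simulate_tissue(cab, t_end = 25, stimuli = stim,
                               probes = 30, record_dt = 0.5)
  cab_c <- set_deformation(make_cable(60, dx = 0.25), 1, 0, 1)
  res_c <- simulate_tissue(cab_c, t_end = 25, stimuli = stim,
                           probes = 30, record_dt = 0.5)
  expect_equal(res_c$trace$V, res_plain$trace$V, tolerance = 1e-10)
})

test_that("Crank-Nicolson diffusion matches an independent dense solver", {
  # pure diffusion of an initial bump: compare against a dense
  # Crank-Nicolson built from the explicit tridiagonal Laplacian, using a
  # resting-but-frozen cell (conductances scaled to zero do not exist, so
  # compare over a very short window where reaction is negligible)
  n <- 40; dx <- 0.25; d <- 1.26; dt <- 0.02
  cab <- make_cable(n, dx = dx, d_l = d)
  cab <- prepace_grid(cab, prepace_beats = 0)
  bump <- 10 * exp(-((seq_len(n) - n / 2)^2) / 8)
  cab$states[, "V"] <- cab$states[, "V"] + bump
  res <- simulate_tissue(cab, t_end = 1, dt = dt, ode_dt = 0.01)
  # dense CN reference with no-flux boundaries for the diffusion part,
  # reaction handled identically through the single-cell stepper
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) { L[i, i - 1] <- d / dx^2; L[i, i] <- L[i, i] - d / dx^2 }
    if (i < n) { L[i, i + 1] <- d / dx^2; L[i, i] <- L[i, i] - d / dx^2 }
  }
  p <- default_cell_parameters()
  st <- lapply(seq_len(n), function(i) {
    s <- cell_initial_state(p); s[["V"]] <- s[["V"]] + bump[i]; s
  })
  A1 <- diag(n) - dt / 2 * L; A2 <- diag(n) + dt / 2 * L
  for (step in 1:(1 / dt)) {
    s_upd <- function(s) gate_step(s, p, dt = 0.01, n = 1L,
                            mech_mode = "isosarcometric")
    st <- lapply(st, s_upd)
    v <- vapply(st, `[[`, numeric(1), "V")
    v <- solve(A1, A2 %*% v)[, 1]
    st <- mapply(function(s, vi) { s[["V"]] <- vi; s }, st, v,
                 SIMPLIFY = FALSE)
    st <- lapply(st, s_upd)
  }
  vref <- vapply(st, `[[`, numeric(1), "V")
  expect_lt(max(abs(res$grid$states[, "V"] - vref)), 0.05)
})

test_that("conduction velocity scales as the square root of conductivity", {
  cab <- make_cable(200, dx = 0.25)
  cv1 <- measure_cv(cab, "x", t_end = 60)$cv
  cab2 <- make_cable(200, dx = 0.25, d_l = 2 * 1.26)
  cv2 <- measure_cv(cab2, "x", t_end = 60)$cv
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.05)
})

test_that("CV converges under grid refinement (halved dx within 3%)", {
  cv1 <- measure_cv(make_cable(160, dx = 0.25), "x", t_end = 40)$cv
  cv2 <- measure_cv(make_cable(320, dx = 0.125), "x", t_end = 40)$cv
  expect_lt(abs(cv1 - cv2) / cv2, 0.03)
})

test_that("anisotropy ratio of 3:1 conductivities gives sqrt(3) CV ratio", {
  sh <- make_sheet(56, 56, dx = 0.25)
  cvx <- measure_cv(sh, "x", t_end = 25)$cv
  cvy <- measure_cv(sh, "y", t_end = 25)$cv
  expect_equal(cvx / cvy, sqrt(3), tolerance = 0.05)
})

test_that("a prescribed stretch C = diag(lambda^2, 1) rescales CV by
           1/lambda", {
  lam <- 1.25
  cv1 <- measure_cv(make_cable(200, dx = 0.25), "x", t_end = 60)$cv
  cab <- set_deformation(make_cable(200, dx = 0.25), lam^2, 0, 1)
  cv2 <- measure_cv(cab, "x", t_end = 60)$cv
  expect_equal(cv2 / cv1, 1 / lam, tolerance = 0.02)
})

test_that("zero stimulus means no activation and an error from measure_cv", {
  cab <- make_cable(120, dx = 0.25)
  expect_error(measure_cv(cab, "x", t_end = 20, stim_amp = 1e-9),
               "no activation")
})

test_that("activation sequence on a heterogeneous RA|PV cable is monotone
           in distance", {
  regions <- c(rep("RA", 60), rep("PV", 60))
  cab <- make_cable(120, dx = 0.25, region_map = regions)
  res <- simulate_tissue(cab, t_end = 40,
                         stimuli = stimulus_event(1:8, 1, amplitude = 40))
  act <- res$t_max_dvdt[10:110]
  expect_true(all(res$act_count[10:110] >= 1))
  expect_true(all(diff(act) >= -1e-9))
})

test_that("the staggered electromechanics exchange feeds shortening back
           into conduction", {
  # gamma = 0 throughout (isosarcometric mode) must equal the uncoupled run
  cab <- make_cable(80, dx = 0.25)
  cab <- prepace_grid(cab, prepace_beats = 1)
  cab$states[, "SL"] <- 1.9 # exactly the resting length, so gamma = 0
  stim <- stimulus_event(1:8, 1, amplitude = 40)
  a <- simulate_tissue(cab, 30, stim, probes = 40, record_dt = 0.5,
                       coupled = TRUE, mech_mode = "isosarcometric")
  b <- simulate_tissue(cab, 30, stim, probes = 40, record_dt = 0.5,
                       coupled = FALSE, mech_mode = "isosarcometric")
  expect_equal(a$trace$V, b$trace$V, tolerance = 1e-9)
  expect_true(all(abs(a$gamma_hist$gamma_mean) < 1e-12))
  # with shortening enabled the coupled run deviates once gamma develops
  cc <- simulate_tissue(cab, 120, stim, probes = 40, record_dt = 0.5,
                        coupled = TRUE, mech_mode = "shortening")
  expect_gt(max(abs(cc$gamma_hist$gamma_mean)), 0.01)
})

test_that("projection between incompatible deformation fields errors", {
  cab <- make_cable(50)
  cab$C <- matrix(1, 10, 3) # wrong node count
  expect_error(simulate_tissue(cab, 5), "tensor|entries|node")
})

test_that("non-SPD deformation tensors are rejected", {
  cab <- set_deformation(make_cable(50), -1, 0, 1)
  expect_error(simulate_tissue(cab, 5), "positive-definite")
  sh <- set_deformation(make_sheet(8, 8), 1, 2, 1) # det < 0
  expect_error(simulate_tissue(sh, 5), "positive-definite")
})
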
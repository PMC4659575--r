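test_that("active strain is the relative sarcomere length change", {
  expect_equal(active_strain(1.9, 1.9), 0)
  expect_equal(active_strain(0.9 * 1.9, 1.9), -0.1)
  expect_equal(active_strain(1.1 * 1.9, 1.9), 0.1) # elongation positive
  expect_error(active_strain(1.9, 0), "SL0")
  expect_equal(active_strain(c(1.9, 1.71), 1.9), c(0, -0.1))
})

test_that("relaxed myofilament at zero Ca produces no force and drives to
           the non-permissive state", {
  p <- default_cell_parameters()
  s <- cell_initial_state(p)
  s[c("XBprer", "XBpostr", "N", "TRPNCaL", "TRPNCaH")] <-
    c(0, 0, 1, 0, 0)
  out <- myofilament_derivatives(s, ca_uM = 0, params = p)
  expect_equal(out$force, 0, tolerance = 1e-12)
  expect_lte(out$derivs[["N"]] * -1, 1e-12) # N does not decrease
  expect_lte(out$derivs[["TRPNCaL"]], 0)
  expect_error(myofilament_derivatives(s, ca_uM = -1), "non-negative")
})

test_that("steady-state force matches the algebraic oracle and is a
           monotone sigmoid of Ca", {
  p <- default_cell_parameters()
  fc <- steady_state_force_calcium(p, ca_grid = 10^seq(-0.6, 1.2,
                                                       length.out = 15),
                                   sl = 2.2, t_end = 3000)
  expect_true(all(diff(fc$force) >= -1e-9)) # monotone non-decreasing
  # integration agrees with the direct algebraic steady state
  for (i in c(3, 8, 12)) {
    want <- oracle_rice_steady_force(fc$ca[i], 2.2, p)
    expect_equal(fc$force[i], want, tolerance = 0.02)
  }
  # near-zero force as Ca -> 0
  f0 <- cpp_rice_clamp(as.numeric(p), 0.01, 2.2, 3000, 0.05, 0L)$force
  expect_lt(f0, 1e-3 * max(fc$force))
  # Hill parameters within the published myofilament-model range
  expect_gt(attr(fc, "hill"), 3)
  expect_lt(attr(fc, "hill"), 10)
  expect_gt(attr(fc, "ca50"), 0.5)
  expect_lt(attr(fc, "ca50"), 5)
})

test_that("saturating Ca gives more force than diastolic Ca", {
  p <- default_cell_parameters()
  f_dia <- cpp_rice_clamp(as.numeric(p), 0.1, 2.2, 2000, 0.05, 0L)$force
  f_sat <- cpp_rice_clamp(as.numeric(p), 20, 2.2, 2000, 0.05, 0L)$force
  expect_gt(f_sat, 10 * max(f_dia, 1e-9))
  expect_lt(f_sat, 1.5) # bounded by the fully-permissive maximum
})

test_that("coupled calcium balance implements the printed term structure", {
  p <- default_cell_parameters()
  zero <- list(I_CaL = 0, I_bCa = 0, I_pCa = 0, I_NaCa = 0, I_up = 0,
               I_leak = 0, I_rel = 0)
  expect_equal(coupled_calcium_derivative(1e-4, zero, 0, p), 0)
  # unit conversion of the troponin flux: dTropCa 1000 uM/ms with zero
  # currents gives -1 mM/ms times the buffering factor
  b <- 1 / (1 + p[["CMDN_max"]] * p[["Km_CMDN"]] /
              (1e-4 + p[["Km_CMDN"]])^2)
  expect_equal(coupled_calcium_derivative(1e-4, zero, 1000, p), -b)
  expect_error(coupled_calcium_derivative(1e-4, zero, NaN, p), "finite")
  # matches the compiled right-hand side on a realistic state
  s <- cell_initial_state(p)
  s[["V"]] <- -20; s[["d"]] <- 0.4; s[["u"]] <- 0.5
  d <- cpp_cell_derivs(as.numeric(s), as.numeric(p), 0, 0L, 1.9)
  cur <- as.list(d$currents)
  expect_equal(coupled_calcium_derivative(s[["Ca_i"]], cur,
                                          cur$dTropTot, p),
               unname(d$derivs[["Ca_i"]]), tolerance = 1e-12)
})

test_that("total Ca is conserved over paced beats within 0.5% of the
           transient amplitude", {
  p <- default_cell_parameters()
  warm <- run_pacing(params = p, protocol = test_protocol(20), dt = 0.02,
                     record_currents = FALSE)
  res <- cpp_cell_run(warm$final_state, as.numeric(p),
                      stim_times = 10, stim_dur = 2, stim_amp = 40,
                      t_end = 1000, dt = 0.001, record_start = 0,
                      record_dt = 0.05, mech_mode = 1L,
                      stim_in_ki = TRUE, record_currents = TRUE)
  tr <- res$trace
  n <- nrow(tr)
  total <- vapply(c(1L, n), function(i) {
    oracle_total_ca(tr[i, ], p)
  }, numeric(1))
  flux <- -p[["Cm"]] * (tr[, "I_CaL"] + tr[, "I_bCa"] + tr[, "I_pCa"] -
                          2 * tr[, "I_NaCa"]) / (2 * p[["F"]])
  dt <- diff(tr[, "t"])
  integral <- sum((flux[-1] + flux[-n]) / 2 * dt)
  amp <- (max(tr[, "Ca_i"]) - min(tr[, "Ca_i"])) * p[["V_i"]]
  err <- abs((total[2] - total[1]) - integral)
  expect_lt(err / amp, 0.005)
})

test_that("gamma stays within physical bounds during an unloaded twitch", {
  res <- run_pacing("RA", "control", test_protocol(10))
  expect_true(all(res$trace$gamma > -1))
  expect_true(all(res$trace$gamma <= 0.2))
  # force non-negative and bounded
  expect_true(all(res$trace$F_active >= 0))
  expect_true(all(res$trace$F_active <= 1.5))
})
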
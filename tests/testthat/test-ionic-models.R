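test_that("regional and remodeling factors are applied exactly once", {
  base <- default_cell_parameters()
  # baseline region with control remodeling is the unmodified base model
  p <- build_cell_parameters("RA/PM", "control")
  expect_equal(as.numeric(p), as.numeric(base))
  # MVR: G_CaL x0.67, G_Kr x2.44, others x1
  p <- build_cell_parameters("MVR", "control")
  expect_equal(p[["g_CaL"]], base[["g_CaL"]] * 0.67)
  expect_equal(p[["g_Kr"]], base[["g_Kr"]] * 2.44)
  expect_equal(p[["g_Na"]], base[["g_Na"]])
  expect_equal(p[["g_to"]], base[["g_to"]])
  # SEP: G_Na x1.5, G_CaL x0.25, G_Kur x0.67
  p <- build_cell_parameters("SEP", "control")
  expect_equal(p[["g_Na"]], base[["g_Na"]] * 1.5)
  expect_equal(p[["g_CaL"]], base[["g_CaL"]] * 0.25)
  expect_equal(p[["g_Kur_sc"]], 0.67)
  # AF on the baseline: channel and Ca-handling factors
  p <- build_cell_parameters("RA", "af")
  expect_equal(p[["g_CaL"]], base[["g_CaL"]] * 0.30)
  expect_equal(p[["g_to"]], base[["g_to"]] * 0.35)
  expect_equal(p[["g_Kur_sc"]], 0.50)
  expect_equal(p[["g_K1"]], base[["g_K1"]] * 2)
  expect_equal(p[["g_Ks"]], base[["g_Ks"]] * 2)
  expect_equal(p[["g_Kr"]], base[["g_Kr"]])
  expect_equal(p[["i_NaCa_max"]], base[["i_NaCa_max"]] * 1.55)
  expect_equal(p[["i_up_max"]], base[["i_up_max"]] * 1.5)
  expect_equal(p[["k_rel"]], base[["k_rel"]] * 4)
})

test_that("regional x remodeling composition equals elementwise product", {
  for (reg in c("MVR", "SEP", "CT-lower-epi", "PV")) {
    p_seq <- build_cell_parameters(reg, "af")
    rp <- region_profiles(); rf <- rp[rp$region == normalize_region(reg), ]
    rm <- remodeling_profiles(); af <- rm[rm$remodeling == "af", ]
    base <- default_cell_parameters()
    expect_equal(p_seq[["g_CaL"]], base[["g_CaL"]] * rf$g_CaL * af$I_CaL)
    expect_equal(p_seq[["g_to"]], base[["g_to"]] * rf$g_to * af$I_to)
    expect_equal(p_seq[["g_Kr"]], base[["g_Kr"]] * rf$g_Kr * af$I_Kr)
  }
})

test_that("unknown regions and conditions raise informative errors", {
  expect_error(build_cell_parameters("LV"), "valid regions")
  expect_error(build_cell_parameters("RA", "chronic"), "valid")
  expect_error(build_cell_parameters("RA", overrides = c(nope = 1)),
               "valid parameter names")
})

test_that("profile invariants hold", {
  rp <- region_profiles()
  expect_true(all(unlist(rp[-1]) > 0))
  expect_equal(unlist(rp[rp$region == "RA", -1], use.names = FALSE),
               rep(1, 5))
  rm <- remodeling_profiles()
  ctl <- unlist(rm[rm$remodeling == "control", -1], use.names = FALSE)
  expect_equal(ctl, rep(1, 10))
})

test_that("compiled currents match an independent R transcription", {
  p <- default_cell_parameters()
  s <- cell_initial_state(p)
  states <- list(
    rest = s,
    depol = replace(s, c("V", "Ca_i"), c(10, 5e-4)),
    plateau = replace(s, c("V", "d", "f", "u", "v"),
                      c(-20, 0.5, 0.6, 0.3, 0.8)),
    af_like = replace(s, c("V", "Na_i", "K_i"), c(-60, 14, 120)))
  for (nm in names(states)) {
    got <- ionic_currents(states[[nm]], p)
    want <- oracle_crn_currents(states[[nm]], p)
    for (cur in names(want))
      expect_equal(got[[cur]], unname(want[[cur]]), tolerance = 1e-12,
                   label = paste(nm, cur))
  }
})

test_that("currents vanish with zero conductances and scale with AF factors", {
  p <- default_cell_parameters()
  s <- cell_initial_state(p)
  s[["V"]] <- -20
  pz <- p
  pz[c("g_Na", "g_to", "g_CaL", "g_Kr", "g_Ks", "g_K1")] <- 1e-300
  pz["g_Kur_sc"] <- 1e-300
  cur <- ionic_currents(s, pz)
  for (nm in c("I_Na", "I_to", "I_CaL", "I_Kr", "I_Ks", "I_K1", "I_Kur"))
    expect_equal(cur[[nm]], 0, tolerance = 1e-200)
  # AF I_CaL is 30% of control at any fixed state
  paf <- build_cell_parameters("RA", "af")
  expect_equal(ionic_currents(s, paf)$I_CaL, 0.30 * ionic_currents(s, p)$I_CaL)
})

test_that("AF peak I_CaL under a voltage-clamp step is 30% of control", {
  p <- default_cell_parameters()
  paf <- build_cell_parameters("RA", "af")
  s <- as.numeric(cell_initial_state(p))
  ctl <- cpp_cell_vclamp(s, as.numeric(p), -80, 10, 20, 60, 0.01, 0.05)
  af <- cpp_cell_vclamp(s, as.numeric(paf), -80, 10, 20, 60, 0.01, 0.05)
  ratio <- min(af$trace[, "I_CaL"]) / min(ctl$trace[, "I_CaL"])
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.35)
})

test_that("resting state is near equilibrium and at published potential", {
  p <- default_cell_parameters()
  # let the model settle without stimulus for 2 s
  s <- gate_step(cell_initial_state(p), p, dt = 0.02, n = 100000L)
  expect_lt(abs(s[["V"]] - (-81.2)), 1.5)
  cur <- ionic_currents(s, p)
  expect_lt(abs(cur$I_ion), 5e-3)
})

test_that("non-finite states are rejected", {
  p <- default_cell_parameters()
  s <- cell_initial_state(p)
  s[["V"]] <- NaN
  expect_error(ionic_currents(s, p), "non-finite")
})

test_that("gates stay in [0,1] under Rush-Larsen and approach steady state", {
  p <- default_cell_parameters()
  s <- cell_initial_state(p)
  # clamp V by zeroing its update: use huge dt and check gate convergence
  res <- cpp_cell_vclamp(as.numeric(s), as.numeric(p), 0, 0, 0, 400,
                         0.05, 1)
  fin <- res$final_state
  gates <- fin[2:16]
  expect_true(all(gates >= 0 & gates <= 1))
  # at fixed depolarised V, activation gates should be far from rest
  expect_gt(fin[["oa"]], 0.5)
  expect_gt(fin[["ua"]], 0.5)
})

test_that("fixed-step integrator matches an adaptive stiff reference solve", {
  skip_if_not_installed("deSolve")
  p <- default_cell_parameters()
  s0 <- cell_initial_state(p)
  # package integrator: one paced beat
  res <- cpp_cell_run(as.numeric(s0), as.numeric(p), stim_times = 10,
                      stim_dur = 2, stim_amp = 40, t_end = 500, dt = 0.002,
                      record_start = 0, record_dt = 0.5, mech_mode = 1L,
                      stim_in_ki = FALSE, record_currents = FALSE)
  tr <- res$trace
  # reference: lsoda at tight tolerance on the same right-hand side
  rhs <- function(t, y, parms) {
    ist <- if (t >= 10 && t < 12) -40 else 0
    list(cpp_cell_derivs(y, parms, ist, 1L, parms[["SL0"]])$derivs)
  }
  ref <- deSolve::lsoda(as.numeric(s0), times = seq(0, 500, 0.5), rhs,
                        p, rtol = 1e-8, atol = 1e-10)
  ref <- ref[match(round(tr[, "t"], 6), round(ref[, 1], 6)), ]
  # compare away from the upstroke (phase shift there dominates)
  sel <- tr[, "t"] < 9 | tr[, "t"] > 20
  dv <- abs(tr[sel, "V"] - ref[sel, 2])
  expect_lt(max(dv), 1.0)
  bm_fix <- compute_biomarkers(data.frame(t = tr[, "t"], V = tr[, "V"],
                                          Ca_i = tr[, "Ca_i"]),
                               stim_times = 10)
  bm_ref <- compute_biomarkers(data.frame(t = ref[, 1], V = ref[, 2],
                                          Ca_i = ref[, "19"]),
                               stim_times = 10)
  expect_lt(abs(bm_fix$apd90 - bm_ref$apd90), 1.0)
  expect_lt(abs(bm_fix$ca_sys / bm_ref$ca_sys - 1), 0.02)
})
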
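test_that("APD90 of a synthetic triangular action potential is analytic", {
  # instantaneous upstroke to +20 mV, linear repolarisation to -80 mV over
  # 200 ms: amplitude 100 mV, 90% repolarisation crossed at 180 ms
  t <- seq(0, 260, 0.25)
  v <- ifelse(t < 1, -80, pmax(20 - 0.5 * (t - 1), -80))
  bm <- compute_biomarkers(data.frame(t = t, V = v), stim_times = 0.75)
  expect_equal(bm$apd90, 180, tolerance = 0.01)
  expect_true(bm$repolarized)
})

test_that("degenerate traces are rejected or flagged", {
  t <- seq(0, 300, 0.5)
  expect_error(compute_biomarkers(data.frame(t = t, V = rep(-80, length(t)))),
               "no action potential")
  # unrepolarised AP: flagged, not silently measured
  v <- ifelse(t < 10, -80, 10) # steps up and never comes back
  bm <- compute_biomarkers(data.frame(t = t, V = v), stim_times = 5)
  expect_false(bm$repolarized)
  expect_true(is.na(bm$apd90))
})

test_that("percent change is the signed control-referenced reduction", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(1, 0.18), 82)
  expect_equal(percent_change(274, 188), 31.4, tolerance = 0.01)
  expect_equal(percent_change(1, 1.5), -50) # increases are negative
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("zero-amplitude stimulation raises a no-capture diagnostic", {
  expect_error(
    run_pacing("RA", "control",
               pacing_protocol(s1_count = 2, stim_amp = 1e-6)),
    "no action potential")
})

test_that("pacing is deterministic and biomarkers are physiological", {
  r1 <- run_pacing("RA", "control", test_protocol(12))
  r2 <- run_pacing("RA", "control", test_protocol(12))
  expect_identical(r1$trace, r2$trace)
  b <- glance(r1)
  expect_gt(b$apd90, 150); expect_lt(b$apd90, 400)
  expect_gt(b$v_rest, -90); expect_lt(b$v_rest, -70)
  expect_gte(b$ca_sys, b$ca_dia)
  expect_gt(b$dvdt_max, 100)
})

test_that("AF remodeling reduces APD, Ca transient and force in every
           region tested", {
  for (reg in c("RA", "LA", "BB-RA")) {
    ctl <- glance(run_pacing(reg, "control", test_protocol(30)))
    af <- glance(run_pacing(reg, "af", test_protocol(30)))
    expect_lt(af$apd90, ctl$apd90)
    expect_lt(af$ca_sys, ctl$ca_sys)
    expect_lt(af$force_peak, ctl$force_peak)
    expect_lt(af$sl_shortening_pct, ctl$sl_shortening_pct)
  }
})

test_that("beat-to-beat APD drift is small near steady state", {
  res <- run_pacing("RA", "control",
                    pacing_protocol(s1_count = 200, record_beats = 10))
  apd <- res$biomarkers$apd90
  expect_lt(max(apd) - min(apd), 1) # < 1 ms over the last 10 beats
})

test_that("biomarkers are insensitive to halving the time step", {
  b1 <- glance(run_pacing("RA", "control", test_protocol(400), dt = 0.02))
  b2 <- glance(run_pacing("RA", "control", test_protocol(400), dt = 0.01))
  expect_lt(abs(b1$apd90 - b2$apd90), 0.5)
})

test_that("gates remain bounded and concentrations positive during pacing", {
  res <- run_pacing("RA", "af", test_protocol(50))
  expect_true(all(res$gate_range$min >= 0))
  expect_true(all(res$gate_range$max <= 1))
  expect_gt(res$gate_range$conc_min, 0)
})

test_that("the region sweep records failures and stays deterministic", {
  sw <- region_sweep(remodeling = "control", protocol = test_protocol(3),
                     regions = c("RA", "MVR"))
  expect_equal(nrow(sw), 2)
  expect_true(all(is.na(sw$error)))
  sw2 <- region_sweep(remodeling = "control", protocol = test_protocol(3),
                      regions = c("RA", "MVR"))
  expect_equal(sw$apd90, sw2$apd90)
  # an invalid region is recorded, not fatal
  sw3 <- region_sweep(remodeling = "control", protocol = test_protocol(2),
                      regions = c("RA", "nowhere"))
  expect_true(any(!is.na(sw3$error)))
  expect_equal(sum(is.na(sw3$error)), 1)
})

test_that("S2 coupling produces an extra premature beat in the trace", {
  res <- run_pacing("RA", "control",
                    pacing_protocol(s1_count = 8, s2_interval = 350,
                                    record_beats = 2))
  # beats recorded: 2 S1 plus the S2
  expect_gte(nrow(res$biomarkers), 3)
  s2 <- res$biomarkers[nrow(res$biomarkers), ]
  s1 <- res$biomarkers[nrow(res$biomarkers) - 1, ]
  expect_lt(s2$apd90, s1$apd90) # premature beat is abbreviated
})
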
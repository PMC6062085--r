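# Trajectory simulation, transient-feature extraction, and in-silico
# knockouts.

test_that("zero stimulus holds the baseline for 100 s", {
  tr <- run_simulation(ref_params, empty_protocol(), t_end = 100)
  expect_false(attr(tr, "diverged"))
  expect_lt(max(abs(tr$FRET)), 0.01)
  expect_lt(max(abs(tr$c - 0.1)) / 0.1, 1e-4)
})

test_that("the reference 30 s pulse shows on-peak, plateau, and off-peak", {
  tr <- run_simulation(ref_params, std_protocol, t_end = 90)
  fe <- extract_features(tr, 10, 40)
  expect_gt(fe$on_max, 8); expect_lt(fe$on_max, 12)
  expect_true(fe$t_on_max > 10 && fe$t_on_max < 40)
  expect_gt(fe$A_plateau, 0.5)
  expect_lt(fe$A_plateau, fe$on_max / 2)
  # distinct off-peak: a genuine rise after withdrawal
  f_end <- tr$FRET[which.min(abs(tr$time - 40))]
  expect_gt(fe$off_max - f_end, 2)
  expect_true(fe$t_off_max > 40)
})

test_that("FRET column is the pointwise conversion of the c column", {
  tr <- run_simulation(ref_params, std_protocol, t_end = 50)
  expect_equal(tr$FRET, c_to_fret(tr$c, std_cal), tolerance = 1e-12)
})

test_that("stored fluxes satisfy the mass-balance identity at every point", {
  tr <- run_simulation(ref_params, std_protocol, t_end = 60, output_dt = 0.5)
  # reconstruct dc/dt by evaluating the RHS at each stored state
  for (i in seq(1, nrow(tr), by = 20)) {
    st <- unlist(tr[i, ashca:::state_names()])
    out <- model_rhs(tr$time[i], st, std_protocol, ref_params)
    stored <- unlist(tr[i, names(out$fluxes)])
    expect_equal(stored, out$fluxes, tolerance = 1e-10)
  }
})

test_that("halving the output grid changes extracted features by < 0.5 %", {
  tr1 <- run_simulation(ref_params, std_protocol, t_end = 90, output_dt = 0.1)
  tr2 <- run_simulation(ref_params, std_protocol, t_end = 90, output_dt = 0.05)
  f1 <- extract_features(tr1, 10, 40)
  f2 <- extract_features(tr2, 10, 40)
  for (nm in c("on_max", "A_plateau", "off_max")) {
    expect_lt(abs(f1[[nm]] - f2[[nm]]) / abs(f2[[nm]]), 0.005)
  }
})

test_that("features of an analytic trapezoid trace match hand computation", {
  t <- seq(0, 60, by = 0.5)
  fr <- approx(x = c(0, 5, 10, 30, 35, 50, 60),
               y = c(0, 8, 4, 4, 6, 1, 1), xout = t)$y
  fe <- extract_features(data.frame(time = t, FRET = fr), 0, 30)
  expect_equal(fe$on_max, 8)
  expect_equal(fe$t_on_max, 5)
  expect_equal(fe$A_plateau, 4)       # final third of the 30 s pulse is flat
  expect_equal(fe$on_decay_slope, (8 - 4) / (10 - 5))
  expect_equal(fe$off_max, 6)
  expect_equal(fe$t_off_max, 35)
  expect_equal(fe$off_rise_slope, (6 - 4) / (35 - 30))
  expect_equal(fe$off_decay_slope, 6 / (50 - 35))
})

test_that("a flat trace yields baseline peaks and zero slopes", {
  t <- seq(0, 70, by = 0.5)
  fe <- extract_features(data.frame(time = t, FRET = rep(0, length(t))), 10, 40)
  expect_equal(fe$on_max, 0)
  expect_equal(fe$off_max, 0)
  expect_equal(fe$on_decay_slope, 0)
  expect_equal(fe$off_rise_slope, 0)
  expect_equal(fe$off_decay_slope, 0)
})

test_that("too-short traces are rejected by feature extraction", {
  t <- seq(0, 45, by = 0.5)
  expect_error(extract_features(data.frame(time = t, FRET = rep(0, length(t))),
                                10, 40), "20 s past")
})

test_that("knockouts zero exactly one conductance and recalibrate", {
  for (comp in c("PMCA", "SERCA", "TRPV", "IPR", "VGCC")) {
    ko <- apply_knockout(ref_params, comp)
    expect_equal(unname(ko$free[[paste0("G_", comp)]]), 0)
    others <- setdiff(free_param_names(), paste0("G_", comp))
    expect_equal(ko$free[others], ref_params$free[others])
    expect_true(ko$calibrated)
  }
  expect_error(apply_knockout(ref_params, "NCX"))
})

test_that("PMCA knockout fails to recover baseline and is flagged", {
  ko <- apply_knockout(ref_params, "PMCA")
  tr <- run_simulation(ko, std_protocol, t_end = 90)
  expect_true(attr(tr, "diverged"))
  expect_gt(tr$c[nrow(tr)], 1)  # cytosolic Ca2+ stays far above baseline
})

test_that("pulse trains show the strongest response to the first pulse", {
  starts <- c(10, 70, 130)
  prot <- stim_train(data.frame(start = starts, duration = 30, magnitude = 1))
  tr <- run_simulation(ref_params, prot, t_end = 200)
  ons <- vapply(starts, function(s) {
    max(tr$FRET[tr$time >= s & tr$time <= s + 30])
  }, numeric(1))
  expect_gt(ons[1], ons[2])
  expect_gt(ons[1], ons[3])
  # later identical pulses give nearly equal off-peak rises
  offr <- vapply(1:2, function(i) {
    e <- starts[i] + 30
    w <- tr$time > e & tr$time <= starts[i + 1]
    max(tr$FRET[w]) - tr$FRET[which.min(abs(tr$time - e))]
  }, numeric(1))
  off3 <- {
    e <- starts[3] + 30
    max(tr$FRET[tr$time > e]) - tr$FRET[which.min(abs(tr$time - e))]
  }
  expect_lt(abs(offr[2] - off3) / off3, 0.05)
})

test_that("trace serialization round-trips losslessly", {
  tr <- run_simulation(ref_params, std_protocol, t_end = 50, output_dt = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$c, tr$c, tolerance = 1e-12)
  expect_equal(back$FRET, tr$FRET, tolerance = 1e-12)
  expect_false(attr(back, "diverged"))
})
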
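# flight times for a synthetic TOF axis: sqrt(mz) exactly cubic in t
.cubic_refs <- function(mz, coef = c(0.5, 0.9, 0.01, 0.001)) {
  # invert numerically: t such that poly3(t) = sqrt(mz)
  t <- vapply(sqrt(mz), function(y)
    uniroot(function(t) coef[1] + coef[2] * t + coef[3] * t^2 +
              coef[4] * t^3 - y, c(0, 100))$root, numeric(1))
  data.frame(flight_time = t, mz = mz)
}

test_that("an exact cubic calibration is recovered to numerical precision", {
  coef <- c(0.5, 0.9, 0.01, 0.001)
  refs <- .cubic_refs(c(159, 200, 322, 450, 622, 703), coef)
  model <- fit_tof_calibration(refs)
  expect_equal(model$coefficients, coef, tolerance = 1e-4)
  expect_lt(max(abs(model$residuals_mda)), 1e-2)
  expect_true(model$monotone)
})

test_that("four references interpolate with zero residuals", {
  refs <- .cubic_refs(c(159, 300, 500, 703))
  refs$mz <- refs$mz + c(0.01, -0.02, 0.03, 0.005)  # perturb: still 4 dof
  model <- fit_tof_calibration(refs)
  expect_lt(max(abs(model$residuals_mda)), 1e-6)
  expect_error(fit_tof_calibration(refs[1:3, ]), "at least 4")
  refs$flight_time[2] <- refs$flight_time[1]
  expect_error(fit_tof_calibration(refs), "distinct")
})

test_that("noisy references fit within the injected noise scale", {
  set.seed(42)
  rms <- vapply(1:100, function(s) {
    refs <- .cubic_refs(seq(159, 703, length.out = 12))
    refs$mz <- refs$mz + rnorm(12, 0, 0.001)  # 1 mDa noise
    model <- fit_tof_calibration(refs)
    sqrt(mean(model$residuals_mda^2))
  }, numeric(1))
  expect_lt(mean(rms), 3 * 1)  # RMS residual within 3x injected 1 mDa
})

test_that("calibration applies, inverts and respects its domain", {
  refs <- .cubic_refs(seq(159, 703, length.out = 8))
  model <- fit_tof_calibration(refs)
  # round trip at interior m/z values
  mz <- c(200, 322.048, 650)
  t <- invert_calibration(model, mz)
  expect_equal(apply_calibration(model, t), mz, tolerance = 1e-9)
  # synthetic truth recovered inside the calibrated range
  expect_lt(max(abs(apply_calibration(model, refs$flight_time) - refs$mz)),
            0.001)
  expect_warning(apply_calibration(model, model$domain[2] + 10),
                 "outside")
  # direct form, constant-plus-linear: value at t = 0 is c0 (not squared)
  dmodel <- fit_tof_calibration(data.frame(flight_time = 1:5,
                                           mz = 10 + 2 * (1:5)),
                                form = "direct")
  expect_equal(apply_calibration(dmodel, 0, warn = FALSE), 10)
  # sqrt form: polynomial value at t squares into m/z
  smodel <- fit_tof_calibration(data.frame(flight_time = 1:6,
                                           mz = (3 + 0.5 * (1:6))^2))
  expect_equal(apply_calibration(smodel, 0, warn = FALSE), 9,
               tolerance = 1e-6)
})

test_that("calibration is strictly increasing on its domain", {
  refs <- .cubic_refs(seq(159, 703, length.out = 10))
  model <- fit_tof_calibration(refs)
  tg <- seq(model$domain[1], model$domain[2], length.out = 200)
  expect_true(all(diff(apply_calibration(model, tg)) > 0))
  # decreasing references flag non-monotonicity
  expect_warning(
    bad <- fit_tof_calibration(data.frame(flight_time = 1:5,
                                          mz = c(500, 400, 300, 200, 159)),
                               form = "direct"),
    "not strictly increasing")
  expect_false(bad$monotone)
})

test_that("built-in lock-mass references recompute from their formulas", {
  expect_equal(round(builtin_lock_mass("P321")$exact_mz, 3), 322.048)
  expect_equal(round(builtin_lock_mass("P621")$exact_mz, 3), 622.029)
  expect_equal(builtin_lock_mass("tetracosenoic")$exact_mz,
               monoisotopic_mass("C24H46O2") - 1.0072765)
})

test_that("lock-mass correction removes a constructed shift and is idempotent", {
  ref <- builtin_lock_mass("P321")
  cfg <- run_config(rbind(sample_ion(400, 5000, 90, 6),
                          lockmass_ion(ref$exact_mz, 60, 60, 0.05)),
                    duration = 180, seed = 8, mass_jitter_sigma = 1)
  run <- generate_run(cfg)

  # unshifted: factor 1 within centroiding noise; exactly 1 when noiseless
  cfg0 <- cfg; cfg0$mass_jitter_sigma <- 0
  run0 <- generate_run(cfg0)
  corr0 <- lock_mass_correct(run0$series, ref)
  expect_equal(attr(corr0, "lockmass_factor"), 1, tolerance = 1e-9)
  expect_equal(corr0$peaks$mz, run0$series$peaks$mz)

  # +2 mDa constructed shift removed to < 0.01 mDa at the reference
  shifted <- run0$series
  shifted$peaks$mz <- shifted$peaks$mz + 0.002
  corr <- lock_mass_correct(shifted, ref)
  peak <- detect_mass_peaks(coadd(corr), min_counts = 100)
  obs <- peak$mz[which.min(abs(peak$mz - ref$exact_mz))]
  expect_lt(abs(obs - ref$exact_mz) * 1000, 0.01)

  # second application: factor 1 within 1e-9
  corr2 <- lock_mass_correct(corr, ref)
  expect_equal(attr(corr2, "lockmass_factor"), 1, tolerance = 1e-9)

  # reference missing from the run
  lonely <- generate_run(run_config(sample_ion(400, 5000, 90, 6),
                                    duration = 180, seed = 8))
  expect_error(lock_mass_correct(lonely$series, ref), "P321")
})
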
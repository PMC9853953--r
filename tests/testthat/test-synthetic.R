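test_that("run generation is deterministic and validates its config", {
  cfg <- tiny_run_config(seed = 11, with_background = TRUE)
  a <- generate_run(cfg)
  b <- generate_run(cfg)
  expect_identical(a$series$peaks, b$series$peaks)
  expect_identical(a$truth, b$truth)
  expect_equal(n_scans(a$series), floor(180 / 0.15))
  expect_error(run_config(sample_ion(400, 1, 90, 6), duration = 0.1,
                          scan_interval = 0.15), "duration")
  empty <- tiny_run_config()
  empty$ions <- empty$ions[0, ]
  expect_error(generate_run(empty), "empty")
})

test_that("zero-amplitude sample ion contributes no counts", {
  cfg <- tiny_run_config(seed = 3, amplitude = 0)
  run <- generate_run(cfg)
  expect_equal(nrow(run$series$peaks), 0L)
  expect_equal(run$truth$total_counts, 0)
})

test_that("total counts match the Poisson expectation over many seeds", {
  A <- 10000
  totals <- vapply(1:200, function(s)
    generate_run(tiny_run_config(seed = s, amplitude = A))$truth$total_counts,
    numeric(1))
  # E[total] = A (elution fully inside the run); 3 sigma band, sigma = sqrt(A)
  expect_lt(abs(mean(totals) - A), 3 * sqrt(A))
})

test_that("expected counts equal the integral of the mean profile", {
  # background ion: plateau + exponential tail integrated over the scan grid
  level <- 40; onset <- 60; rate <- 0.05; dur <- 180; dt <- 0.15
  times <- (seq_len(floor(dur / dt)) - 1L) * dt
  expected <- sum(ifelse(times <= onset, level,
                         level * exp(-rate * (times - onset))))
  cfg <- run_config(background_ion(300, level, onset, rate), duration = dur)
  totals <- vapply(1:100, function(s) {
    cfg$seed <- s
    generate_run(cfg)$truth$total_counts
  }, numeric(1))
  expect_lt(abs(mean(totals) - expected), 3 * sqrt(expected))
})

test_that("background ions decay after their onset", {
  cfg <- run_config(background_ion(300, 50, decay_onset = 60,
                                   decay_rate = 0.05),
                    duration = 180, seed = 5)
  run <- generate_run(cfg)
  prof <- extract_ion_profile(run$series, 300, 5)
  early <- mean(prof$counts[prof$times < 60])
  late <- mean(prof$counts[prof$times >= 120])
  expect_gte(early, late)
})

test_that("blank runs drop sample ions and keep the rest", {
  cfg <- tiny_run_config(seed = 21, with_background = TRUE)
  blank <- generate_blank_run(cfg)
  expect_setequal(blank$truth$kind, c("background", "lockmass"))
  expect_equal(nrow(blank$truth), 2L)
  # blank truth = sample-run truth minus sample ions (same specs)
  full <- generate_run(cfg)
  expect_equal(blank$truth$mz_true,
               full$truth$mz_true[full$truth$kind != "sample"])
  # no blank scan carries a peak near the sample ion's m/z (jitter window)
  expect_false(any(abs(blank$series$peaks$mz - 400) <= 0.05))
  # with no sample ions, blank and run are the same draw
  cfg2 <- run_config(rbind(background_ion(199.17, 50, 60, 0.05),
                           lockmass_ion(322.0481, 60, 60, 0.05)),
                     duration = 120, seed = 9)
  expect_identical(generate_blank_run(cfg2)$series$peaks,
                   generate_run(cfg2)$series$peaks)
})

test_that("mass-axis distortion is applied to observed m/z", {
  # pure offset distortion: every observed m/z shifted by +0.002
  cfg <- tiny_run_config(seed = 2)
  cfg$calibration_distortion <- c(0.002, 1, 0, 0)
  cfg$mass_jitter_sigma <- 0
  run <- generate_run(cfg)
  expect_true(all(abs(run$series$peaks$mz - 400.002) < 1e-9))
})

test_that("structure fixture is deterministic and exercises all branches", {
  a <- make_structure_fixture(8, seed = 4)
  b <- make_structure_fixture(8, seed = 4)
  expect_identical(a, b)
  expect_equal(sum(a == "$$$$"), 8L)
  # multi-fragment (salt), deuterated, and duplicated-formula records exist
  expect_true(any(grepl("salt", a)))
  expect_true(any(grepl("-d3", a)))
  path <- withr::local_tempfile(fileext = ".sdf")
  make_structure_fixture(4, seed = 4, path = path)
  expect_identical(readLines(path), make_structure_fixture(4, seed = 4))
})
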
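test_that("flat and empty profiles yield no elution peak", {
  flat <- structure(list(target_mz = 400, halfwidth_mda = 5,
                         times = seq(0, 30, 0.15),
                         counts = rep(20, 201)),
                    class = "ExtractionProfile")
  expect_null(detect_elution_peak(flat))
  zero <- flat; zero$counts <- rep(0, 201)
  expect_null(detect_elution_peak(zero))
  short <- flat; short$times <- flat$times[1:3]; short$counts <- rep(1, 3)
  expect_error(detect_elution_peak(short), "at least 5 scans")
})

test_that("noiseless Gaussian FWHM matches the closed form", {
  for (sigma in c(3, 6, 10)) {
    pk <- detect_elution_peak(gaussian_profile(sigma = sigma))
    expect_lt(abs(pk$fwhm - 2.3548 * sigma), 0.15, label = paste("sigma", sigma))
    expect_lt(pk$half_height_start, pk$apex_time)
    expect_gt(pk$half_height_end, pk$apex_time)
  }
})

test_that("peak area recovers the ground-truth FWHM-window counts", {
  # smoothing window matched to the expected peak width (~FWHM/4) keeps
  # the apex estimate unbiased; see the methods vignette
  for (seed in c(101, 202, 303)) {
    run <- generate_run(tiny_run_config(seed = seed, amplitude = 10000))
    pk <- detect_elution_peak(extract_ion_profile(run$series, 400, 5),
                              smoothing_window = 21)
    truth <- run$truth$fwhm_counts
    expect_lt(abs(pk$area_counts - truth), 3 * sqrt(truth))
    expect_lte(pk$area_counts, run$truth$total_counts)
  }
})

test_that("ions classify as sample, background or unclassified", {
  run <- generate_run(tiny_run_config(seed = 31, with_background = TRUE))
  cls <- function(mz) classify_ion(extract_ion_profile(run$series, mz, 5))
  expect_equal(cls(400)$classification, "sample")
  expect_equal(cls(199.17)$classification, "background")
  expect_equal(cls(322.0481)$classification, "background")
  expect_equal(cls(777)$classification, "unclassified")  # all-zero profile
})

test_that("blank matching follows the +/-5 mDa window", {
  ions <- data.frame(mz = c(303.233, 310.000),
                     total_counts = c(100, 50),
                     classification = c("sample", "sample"),
                     stringsAsFactors = FALSE)
  # 3 mDa away: matched; 7 mDa away: not
  out <- match_blank(ions, data.frame(mz = 303.236), tolerance_mda = 5)
  expect_equal(out$classification, c("blank_matched", "sample"))
  expect_equal(out$matched_blank_mz[1], 303.236)
  out2 <- match_blank(ions, data.frame(mz = 303.240), tolerance_mda = 5)
  expect_equal(out2$classification, c("sample", "sample"))
  # empty blank: untouched
  out3 <- match_blank(ions, data.frame(mz = numeric(0)))
  expect_equal(out3$classification, ions$classification)
  # equidistant blank ions: tie resolved to the lower m/z
  out4 <- match_blank(data.frame(mz = 400, total_counts = 1,
                                 classification = "sample"),
                      data.frame(mz = c(399.998, 400.002)))
  expect_equal(out4$matched_blank_mz, 399.998)
})

test_that("blank matching agrees with the brute-force all-pairs oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n_s <- sample(50:300, 1); n_b <- sample(50:300, 1)
    smz <- sort(runif(n_s, 100, 110))
    bmz <- sort(runif(n_b, 100, 110))
    ions <- data.frame(mz = smz, total_counts = 1,
                       classification = "sample", stringsAsFactors = FALSE)
    got <- match_blank(ions, data.frame(mz = bmz), tolerance_mda = 5)
    oracle <- rowSums(brute_force_pairs(smz, bmz, 5)) > 0
    expect_equal(got$classification == "blank_matched", unname(oracle))
  }
})

test_that("reported area never exceeds the profile total", {
  for (seed in 1:10) {
    run <- generate_run(tiny_run_config(seed = seed, amplitude = 3000,
                                        with_background = TRUE))
    for (mz in run$truth$mz_true) {
      prof <- extract_ion_profile(run$series, mz, 5)
      pk <- detect_elution_peak(prof)
      if (!is.null(pk)) expect_lte(pk$area_counts, sum(prof$counts))
    }
  }
})
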
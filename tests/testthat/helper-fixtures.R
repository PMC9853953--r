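# Shared fixtures: tiny deterministic runs and a hand-built series whose
# counts are known exactly.

# one sample ion, optionally with background and lockmass company
tiny_run_config <- function(seed = 1L, amplitude = 10000, sigma = 6,
                            with_background = FALSE, duration = 180) {
  ions <- sample_ion(400, amplitude, center = duration / 2, sigma = sigma)
  if (with_background)
    ions <- rbind(ions,
                  background_ion(199.17, 50, duration / 3, 0.05),
                  lockmass_ion(322.0481, 60, duration / 3, 0.05))
  run_config(ions, duration = duration, seed = seed)
}

# a 3-scan series with hand-placed peaks (counts known exactly)
hand_series <- function() {
  spectrum_series(
    data.frame(scan = c(1L, 1L, 2L, 3L),
               mz = c(100.000, 200.000, 100.000, 100.200),
               counts = c(3, 5, 7, 11)),
    scan_times = c(0, 0.15, 0.30))
}

# noiseless Gaussian extraction profile (non-integer counts are fine for
# the peak detector)
gaussian_profile <- function(sigma = 6, amplitude = 10000, duration = 180,
                             dt = 0.15) {
  times <- seq(0, duration - dt, by = dt)
  structure(
    list(target_mz = 400, halfwidth_mda = 5, times = times,
         counts = amplitude * dnorm(times, duration / 2, sigma) * dt),
    class = "ExtractionProfile")
}

# brute-force all-pairs |delta mz| <= tol matcher, the oracle for
# match_blank and match_ions
brute_force_pairs <- function(a_mz, b_mz, tol_mda) {
  hits <- matrix(FALSE, length(a_mz), length(b_mz))
  for (i in seq_along(a_mz))
    for (j in seq_along(b_mz))
      hits[i, j] <- abs(a_mz[i] - b_mz[j]) * 1000 <= tol_mda
  hits
}
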
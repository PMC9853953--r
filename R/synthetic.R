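# Synthetic SFE-PTR MS run generator.
#
# Emulates what the downstream analysis consumes: already-centroided
# (m/z, counts) pairs per 0.15 s scan, with Poisson counting noise. Three
# ion kinds reproduce the qualitative behaviour seen in real runs:
#   sample   - Gaussian (bell-shaped) elution pulse from the extraction,
#   background - reagent/instrument ions held constant early in the run,
#              then decaying exponentially once analytes arrive,
#   lockmass - reference compound, same temporal model as background.
# The generator also returns the hidden ground truth so recovery can be
# scored.

#' Specify one synthetic ion
#'
#' Constructors for the per-ion specifications consumed by [run_config()].
#' `sample_ion()` ions elute as a Gaussian pulse carrying an expected
#' `amplitude` total counts; `background_ion()` and `lockmass_ion()` ions
#' sit at a constant per-scan level until `decay_onset`, then decay
#' exponentially at `decay_rate`.
#'
#' @param mz True m/z in Da.
#' @param amplitude Expected total ion counts over the whole run (>= 0).
#' @param center Elution apex time in s.
#' @param sigma Gaussian elution width (standard deviation) in s, > 0.
#'   The full width at half maximum is `2.3548 * sigma`.
#' @param level Expected counts per scan during the plateau (>= 0).
#' @param decay_onset Time (s) at which the level starts decaying.
#' @param decay_rate Exponential decay rate in 1/s (>= 0).
#' @return One-row data frame (an ion spec); rows are concatenated into the
#'   `ions` table of a run configuration.
#' @name ion-specs
NULL

#' @rdname ion-specs
#' @export
sample_ion <- function(mz, amplitude, center, sigma) {
  stopifnot(amplitude >= 0, sigma > 0)
  data.frame(mz_true = mz, kind = "sample", amplitude = amplitude,
             elution_center = center, elution_width_sigma = sigma,
             background_level = 0, decay_onset = NA_real_,
             decay_rate = NA_real_, stringsAsFactors = FALSE)
}

#' @rdname ion-specs
#' @export
background_ion <- function(mz, level, decay_onset, decay_rate) {
  stopifnot(level >= 0, decay_rate >= 0)
  data.frame(mz_true = mz, kind = "background", amplitude = NA_real_,
             elution_center = NA_real_, elution_width_sigma = NA_real_,
             background_level = level, decay_onset = decay_onset,
             decay_rate = decay_rate, stringsAsFactors = FALSE)
}

#' @rdname ion-specs
#' @export
lockmass_ion <- function(mz, level, decay_onset, decay_rate) {
  out <- background_ion(mz, level, decay_onset, decay_rate)
  out$kind <- "lockmass"
  out
}

#' Configure a synthetic run
#'
#' @param ions Data frame of ion specs (rbind of [sample_ion()],
#'   [background_ion()], [lockmass_ion()] rows).
#' @param duration Run duration in s.
#' @param scan_interval Scan interval in s (default 0.15).
#' @param polarity `"positive"` or `"negative"`.
#' @param mass_jitter_sigma Per-scan Gaussian m/z jitter, in mDa (>= 0).
#' @param calibration_distortion Length-4 numeric: coefficients
#'   `c(c0, c1, c2, c3)` of a third-order polynomial applied to every
#'   observed m/z, emulating a miscalibrated mass axis. The default
#'   `c(0, 1, 0, 0)` is the identity.
#' @param seed Integer seed for the run's single random stream.
#' @return Object of class `SyntheticRunConfig`.
#' @export
run_config <- function(ions, duration, scan_interval = 0.15,
                       polarity = c("positive", "negative"),
                       mass_jitter_sigma = 1,
                       calibration_distortion = c(0, 1, 0, 0),
                       seed = 1L) {
  polarity <- match.arg(polarity)
  if (!(duration > scan_interval && scan_interval > 0))
    stop("need duration > scan_interval > 0")
  if (mass_jitter_sigma < 0) stop("mass_jitter_sigma must be >= 0")
  stopifnot(length(calibration_distortion) == 4)
  structure(
    list(ions = ions, duration = duration, scan_interval = scan_interval,
         polarity = polarity, mass_jitter_sigma = mass_jitter_sigma,
         calibration_distortion = as.numeric(calibration_distortion),
         seed = as.integer(seed)),
    class = "SyntheticRunConfig")
}

# expected counts per scan for one ion spec over the scan-time grid
.ion_mean_profile <- function(spec, times, dt) {
  if (spec$kind == "sample") {
    spec$amplitude * stats::dnorm(times, spec$elution_center,
                                  spec$elution_width_sigma) * dt
  } else {
    lev <- rep(spec$background_level, length(times))
    late <- times > spec$decay_onset
    lev[late] <- spec$background_level *
      exp(-spec$decay_rate * (times[late] - spec$decay_onset))
    lev
  }
}

.poly3 <- function(coef, x) coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3

#' Generate a synthetic SFE-PTR MS run
#'
#' Draws a full run from a configuration: `floor(duration / scan_interval)`
#' scans; for each ion, per-scan counts are Poisson with mean following its
#' elution model, and the observed m/z is the true m/z plus per-scan
#' Gaussian jitter, passed through the configured mass-axis distortion
#' polynomial.
#'
#' Draw order (fixed, so runs regenerate exactly from `(config, seed)`):
#' ions are processed in table order; for each ion, first the Poisson
#' counts for all scans, then the m/z jitter for all scans.
#'
#' @param config A `SyntheticRunConfig`.
#' @return List with elements `series` (a [spectrum_series()]) and `truth`
#'   (a `GroundTruth` data frame: one row per ion with its spec, the
#'   realised total counts, and the realised counts inside the elution
#'   FWHM window for sample ions).
#' @export
generate_run <- function(config) {
  stopifnot(inherits(config, "SyntheticRunConfig"))
  ions <- config$ions
  if (is.null(ions) || nrow(ions) == 0L) stop("ion list is empty")
  n <- floor(config$duration / config$scan_interval)
  dt <- config$scan_interval
  times <- (seq_len(n) - 1L) * dt

  set.seed(config$seed)
  peaks <- vector("list", nrow(ions))
  truth <- ions
  truth$total_counts <- NA_real_
  truth$fwhm_counts <- NA_real_
  truth$true_amount <- NA_real_
  for (i in seq_len(nrow(ions))) {
    spec <- ions[i, ]
    mu <- .ion_mean_profile(spec, times, dt)
    counts <- stats::rpois(n, mu)
    jitter <- stats::rnorm(n, 0, config$mass_jitter_sigma / 1000)
    mz_obs <- .poly3(config$calibration_distortion, spec$mz_true + jitter)
    keep <- counts > 0L
    peaks[[i]] <- data.frame(scan = which(keep), mz = mz_obs[keep],
                             counts = counts[keep])
    truth$total_counts[i] <- sum(counts)
    if (spec$kind == "sample") {
      half <- 2.3548200450309493 * spec$elution_width_sigma / 2
      win <- abs(times - spec$elution_center) <= half
      truth$fwhm_counts[i] <- sum(counts[win])
    }
  }
  series <- spectrum_series(do.call(rbind, peaks), times,
                            polarity = config$polarity,
                            scan_interval = dt)
  class(truth) <- c("GroundTruth", "data.frame")
  list(series = series, truth = truth)
}

#' Generate the matching blank run
#'
#' Same configuration with every sample ion removed: the blank frit still
#' carries the lock-mass reference and sees the same reagent/instrument
#' background, but no analyte elutes. Uses the same seed convention as
#' [generate_run()], so a configuration with no sample ions yields an
#' identical run.
#'
#' @param config A `SyntheticRunConfig`.
#' @return As [generate_run()]; the ground truth contains only the
#'   retained (non-sample) ions.
#' @export
generate_blank_run <- function(config) {
  stopifnot(inherits(config, "SyntheticRunConfig"))
  if (is.null(config$ions) || nrow(config$ions) == 0L) stop("ion list is empty")
  blank <- config
  blank$ions <- config$ions[config$ions$kind != "sample", ]
  if (nrow(blank$ions) == 0L)
    stop("blank run would contain no ions (no background or lockmass ions)")
  generate_run(blank)
}
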
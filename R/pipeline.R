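# End-to-end screening pipeline: lock-mass correction, co-addition, mass
# peak detection, per-ion XIC classification, blank matching, annotation,
# quantitation. This is the programmatic surface behind the command-line
# interface in inst/cli/sfeptr.R.

#' Pipeline configuration
#'
#' All tunable tolerances and detection settings in one place. Defaults
#' follow the screening procedure: +/-5 mDa blank matching, 3 mDa
#' annotation tolerance, LOQ at 100 counts.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param blank_match_mda Blank-match half-window, mDa (default 5).
#' @param annotate_mda Annotation match half-window, mDa (default 3).
#' @param loq_counts Counts defining the limit of quantitation (default 100).
#' @param coadd_bin_mda Co-addition bin width, mDa (default 5).
#' @param xic_halfwidth_mda XIC window half-width, mDa (default 5).
#' @param min_peak_counts Minimum co-added counts for a mass peak
#'   (default 50).
#' @param smoothing_window XIC smoothing window, scans (default 5).
#' @param snr_min Minimum elution-peak signal-to-noise (default 3).
#' @param lockmass_window_mda Lock-mass search half-window, mDa (default 20).
#' @param include_ammonium Allow the `[M+NH4]+` species (default `FALSE`).
#' @param annotation_gate `"fixed"` or `"replicate_sd"` (see [match_ions()]).
#' @return A named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(polarity = "positive",
                            blank_match_mda = 5,
                            annotate_mda = 3,
                            loq_counts = 100,
                            coadd_bin_mda = 5,
                            xic_halfwidth_mda = 5,
                            min_peak_counts = 50,
                            smoothing_window = 5,
                            snr_min = 3,
                            lockmass_window_mda = 20,
                            include_ammonium = FALSE,
                            annotation_gate = "fixed") {
  cfg <- list(polarity = polarity, blank_match_mda = blank_match_mda,
              annotate_mda = annotate_mda, loq_counts = loq_counts,
              coadd_bin_mda = coadd_bin_mda,
              xic_halfwidth_mda = xic_halfwidth_mda,
              min_peak_counts = min_peak_counts,
              smoothing_window = smoothing_window, snr_min = snr_min,
              lockmass_window_mda = lockmass_window_mda,
              include_ammonium = include_ammonium,
              annotation_gate = annotation_gate)
  tol <- c("blank_match_mda", "annotate_mda", "loq_counts", "coadd_bin_mda",
           "xic_halfwidth_mda", "lockmass_window_mda")
  for (k in tol) if (cfg[[k]] <= 0) stop(k, " must be > 0")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys take [pipeline_config()]
#' defaults; `overrides` (named list) wins over the file.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list of settings overriding the file.
#' @return A `PipelineConfig`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Screen a sample run against a blank run
#'
#' The full classification procedure: both runs are lock-mass corrected
#' (when a reference is given), the sample run is co-added and its mass
#' peaks detected, each peak's extracted ion profile is classified as
#' sample / background / unclassified, and peaks also present in the
#' blank's co-added spectrum within the blank tolerance are demoted to
#' `blank_matched`.
#'
#' @param sample_series,blank_series `SpectrumSeries` of the same polarity
#'   (`blank_series` may be `NULL`: no blank matching).
#' @param lockmass Optional `LockMassReference` applied to both runs.
#' @param config A [pipeline_config()].
#' @return Screening report data frame: `mz`, `total_counts`,
#'   `classification`, `apex_time`, `fwhm`, `area`, `matched_blank_mz`,
#'   one row per detected ion, sorted by m/z.
#' @export
screen_run <- function(sample_series, blank_series = NULL, lockmass = NULL,
                       config = pipeline_config()) {
  stopifnot(inherits(sample_series, "SpectrumSeries"))
  if (!is.null(blank_series) &&
      blank_series$polarity != sample_series$polarity)
    stop("sample and blank runs have different polarities")
  if (!is.null(lockmass)) {
    sample_series <- lock_mass_correct(sample_series, lockmass,
                                       config$lockmass_window_mda)
    if (!is.null(blank_series))
      blank_series <- lock_mass_correct(blank_series, lockmass,
                                        config$lockmass_window_mda)
  }
  ions <- detect_mass_peaks(
    coadd(sample_series, bin_width_mda = config$coadd_bin_mda),
    min_counts = config$min_peak_counts)
  ions$apex_time <- NA_real_
  ions$fwhm <- NA_real_
  ions$area <- NA_real_
  for (i in seq_len(nrow(ions))) {
    prof <- extract_ion_profile(sample_series, ions$mz[i],
                                config$xic_halfwidth_mda)
    cls <- classify_ion(prof, config$smoothing_window, config$snr_min)
    ions$classification[i] <- cls$classification
    if (!is.null(cls$peak)) {
      ions$apex_time[i] <- cls$peak$apex_time
      ions$fwhm[i] <- cls$peak$fwhm
      ions$area[i] <- cls$peak$area_counts
    }
  }
  if (!is.null(blank_series)) {
    blank_ions <- detect_mass_peaks(
      coadd(blank_series, bin_width_mda = config$coadd_bin_mda),
      min_counts = config$min_peak_counts)
    ions <- match_blank(ions, blank_ions, config$blank_match_mda)
  } else {
    ions$matched_blank_mz <- NA_real_
  }
  ions
}

#' Annotate sample-classified ions from a screening report
#'
#' Only ions classified `"sample"` are annotated, against candidates
#' enumerated from a normalised structure database at the configured
#' polarity and tolerance. Output columns mirror the screening tables:
#' observed m/z, replicate SD, formula, species, isomer count, exact m/z.
#'
#' @param screening Screening report from [screen_run()], or a data frame
#'   with at least `mz` and `classification` columns (optionally `sd_mda`,
#'   `n` from replicate merging).
#' @param sdf Structure database: path / SDF text / `SDFset` (passed to
#'   [normalize_structures()]).
#' @param config A [pipeline_config()].
#' @return Annotation table from [match_ions()].
#' @export
annotate_screening <- function(screening, sdf, config = pipeline_config()) {
  formulas <- normalize_structures(sdf)
  candidates <- build_candidates(formulas, config$polarity,
                                 include_ammonium = config$include_ammonium)
  sel <- screening[screening$classification == "sample", , drop = FALSE]
  observed <- data.frame(
    mz_mean = sel$mz,
    sd_mda = if ("sd_mda" %in% names(sel)) sel$sd_mda
             else rep(NA_real_, nrow(sel)),
    n = if ("n" %in% names(sel)) sel$n else rep(NA_integer_, nrow(sel)))
  observed <- observed[order(observed$mz_mean), ]
  match_ions(observed, candidates, tolerance_mda = config$annotate_mda,
             gate = config$annotation_gate)
}

#' Default synthetic study conditions
#'
#' The run configuration used throughout the test-bench: a 180 s
#' extraction at the 0.15 s scan interval, sample ions eluting as Gaussian
#' pulses (apex 90 s, sigma 6 s), reagent/background ions at 50 counts per
#' scan decaying from 60 s at 0.05 /s, a lock-mass reference ion, and 1
#' mDa per-scan mass jitter.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param seed Integer seed.
#' @param sample_mz,sample_amplitude m/z (Da) and expected total counts of
#'   the sample ions.
#' @param background_mz m/z of the background ions.
#' @param lockmass_mz m/z of the lock-mass ion (default: P321 `[M+H]+`
#'   for positive mode, deprotonated tetracosenoic acid for negative).
#' @return A [run_config()].
#' @export
study_run_config <- function(polarity = "positive", seed = 1L,
                             sample_mz = c(303.2330, 282.2794, 425.3412),
                             sample_amplitude = rep(20000, length(sample_mz)),
                             background_mz = c(199.1700, 250.9000),
                             lockmass_mz = NULL) {
  if (is.null(lockmass_mz)) {
    lockmass_mz <- if (polarity == "positive")
      builtin_lock_mass("P321")$exact_mz
    else
      builtin_lock_mass("tetracosenoic")$exact_mz
  }
  ions <- do.call(rbind, c(
    lapply(seq_along(sample_mz), function(i)
      sample_ion(sample_mz[i], sample_amplitude[i], center = 90, sigma = 6)),
    lapply(background_mz, function(m)
      background_ion(m, level = 50, decay_onset = 60, decay_rate = 0.05)),
    list(lockmass_ion(lockmass_mz, level = 60, decay_onset = 60,
                      decay_rate = 0.05))))
  run_config(ions, duration = 180, scan_interval = 0.15,
             polarity = polarity, mass_jitter_sigma = 1, seed = seed)
}
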
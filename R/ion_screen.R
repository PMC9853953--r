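# Classification of observed ions from their extracted ion profiles.
#
# Sample-derived ions elute from the extraction as a bell-shaped pulse;
# reagent and instrument background ions are present from the start of the
# run and decay once analytes arrive. Screening therefore asks, per ion:
# does the XIC carry a genuine chromatographic peak (sample), does it
# decay from an initial plateau (background), or neither (unclassified)?
# Sample-classified ions that also appear in a blank run within a narrow
# m/z tolerance are demoted to blank_matched.

# centered moving average; edge windows shrink to what is available
.moving_average <- function(x, window) {
  if (window <= 1L) return(as.numeric(x))
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# first time the smoothed trace crosses `level`, scanning away from the
# apex; linear interpolation between the bracketing scans
.crossing_time <- function(times, y, apex_idx, level, direction) {
  idx <- if (direction == "left") seq(apex_idx, 1L) else seq(apex_idx, length(y))
  below <- which(y[idx] < level)
  if (length(below) == 0L) return(NA_real_)
  j <- idx[below[1L]]                       # first scan below level
  k <- if (direction == "left") j + 1L else j - 1L  # last scan at/above level
  # interpolate between scans j and k
  if (y[k] == y[j]) return(times[j])
  frac <- (y[k] - level) / (y[k] - y[j])
  times[k] + frac * (times[j] - times[k])
}

#' Detect an elution peak in an extracted ion profile
#'
#' The profile is smoothed by a centered moving average; the global maximum
#' of the smoothed trace is the candidate apex and the median of the
#' smoothed trace is the baseline. The candidate is accepted as a peak iff
#' its Poisson signal-to-noise `(apex - baseline) / sqrt(baseline + 1)` is
#' at least `snr_min` AND the smoothed trace falls below the half height
#' `baseline + (apex - baseline) / 2` on both sides of the apex within the
#' run. Half-height crossing times are found by linear interpolation on the
#' smoothed trace; the reported area is the sum of RAW counts between the
#' two crossings.
#'
#' @param profile An [extract_ion_profile()] result, at least 5 scans long.
#' @param smoothing_window Moving-average width in scans (default 5,
#'   about 0.75 s at the 0.15 s scan interval).
#' @param snr_min Minimum Poisson signal-to-noise at the apex (default 3).
#' @return An `ElutionPeak` (list with `apex_time`, `apex_counts`,
#'   `half_height_start`, `half_height_end`, `fwhm`, `area_counts`,
#'   `baseline`) or `NULL` when no peak qualifies.
#' @export
detect_elution_peak <- function(profile, smoothing_window = 5, snr_min = 3) {
  stopifnot(inherits(profile, "ExtractionProfile"))
  y <- profile$counts
  if (length(y) < 5L) stop("profile must span at least 5 scans")
  sm <- .moving_average(y, smoothing_window)
  baseline <- stats::median(sm)
  apex_idx <- which.max(sm)
  apex <- sm[apex_idx]
  if ((apex - baseline) / sqrt(baseline + 1) < snr_min) return(NULL)
  half <- baseline + (apex - baseline) / 2
  t_left <- .crossing_time(profile$times, sm, apex_idx, half, "left")
  t_right <- .crossing_time(profile$times, sm, apex_idx, half, "right")
  if (is.na(t_left) || is.na(t_right)) return(NULL)
  in_win <- profile$times >= t_left & profile$times <= t_right
  structure(
    list(apex_time = profile$times[apex_idx], apex_counts = apex,
         half_height_start = t_left, half_height_end = t_right,
         fwhm = t_right - t_left, area_counts = sum(y[in_win]),
         baseline = baseline),
    class = "ElutionPeak")
}

#' Classify one ion from its extracted ion profile
#'
#' `"sample"` when [detect_elution_peak()] finds a peak; otherwise
#' `"background"` when the mean counts in the first `decile` fraction of
#' scans exceed `decay_ratio` times the mean in the last fraction (and the
#' early mean is positive), operationalising "held at the start, then
#' decaying"; otherwise `"unclassified"`.
#'
#' @param profile An `ExtractionProfile`.
#' @param smoothing_window,snr_min Passed to [detect_elution_peak()].
#' @param decay_ratio Early/late mean ratio declaring decay (default 2).
#' @param decile Fraction of scans in the early/late windows (default 0.1).
#' @return List with `classification` (`"sample"`, `"background"`, or
#'   `"unclassified"`) and `peak` (the `ElutionPeak` or `NULL`).
#' @export
classify_ion <- function(profile, smoothing_window = 5, snr_min = 3,
                         decay_ratio = 2, decile = 0.1) {
  stopifnot(inherits(profile, "ExtractionProfile"))
  n <- length(profile$counts)
  if (n == 0L) stop("empty profile")
  peak <- detect_elution_peak(profile, smoothing_window, snr_min)
  if (!is.null(peak))
    return(list(classification = "sample", peak = peak))
  k <- max(1L, floor(n * decile))
  early <- mean(profile$counts[seq_len(k)])
  late <- mean(profile$counts[seq.int(n - k + 1L, n)])
  if (early > 0 && early > decay_ratio * late)
    list(classification = "background", peak = NULL)
  else
    list(classification = "unclassified", peak = NULL)
}

#' Flag sample ions that also appear in the blank run
#'
#' Every sample-list ion with at least one blank-list ion within
#' `tolerance_mda` is reclassified `blank_matched`; the nearest blank m/z
#' is reported (ties resolved to the lower m/z). Other ions pass through
#' untouched.
#'
#' @param sample_ions,blank_ions Ion-record data frames (column `mz`,
#'   sorted by m/z) as returned by [detect_mass_peaks()] / [screen_run()].
#' @param tolerance_mda Match window half-width in mDa (default 5).
#' @return `sample_ions` with updated `classification` and a
#'   `matched_blank_mz` column (NA where unmatched).
#' @export
match_blank <- function(sample_ions, blank_ions, tolerance_mda = 5) {
  tol <- tolerance_mda / 1000
  out <- sample_ions
  out$matched_blank_mz <- NA_real_
  if (nrow(sample_ions) == 0L || nrow(blank_ions) == 0L) return(out)
  bmz <- sort(blank_ions$mz)
  for (i in seq_len(nrow(out))) {
    d <- abs(bmz - out$mz[i])
    j <- which(d <= tol)
    if (length(j)) {
      best <- j[d[j] == min(d[j])]
      out$matched_blank_mz[i] <- bmz[min(best)]  # tie -> lower m/z
      out$classification[i] <- "blank_matched"
    }
  }
  out
}
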
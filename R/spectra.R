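#' Construct a spectrum series
#'
#' A `SpectrumSeries` holds one acquisition run of centroided TOF scans for
#' one polarity: a long table of per-scan peaks plus the full scan-time
#' grid (scans with no peaks above threshold still occupy a grid slot, which
#' extracted-ion profiles rely on).
#'
#' @param peaks Data frame with columns `scan` (1-based scan index), `mz`
#'   (Da) and `counts` (non-negative integers).
#' @param scan_times Numeric vector of scan start times (s), strictly
#'   increasing, one per scan in the run.
#' @param polarity `"positive"` or `"negative"`.
#' @param scan_interval Scan interval in seconds (default 0.15).
#' @return Object of class `SpectrumSeries`.
#' @export
spectrum_series <- function(peaks, scan_times,
                            polarity = c("positive", "negative"),
                            scan_interval = 0.15) {
  polarity <- match.arg(polarity)
  stopifnot(is.data.frame(peaks),
            all(c("scan", "mz", "counts") %in% names(peaks)))
  if (any(diff(scan_times) <= 0))
    stop("scan_times must be strictly increasing")
  if (nrow(peaks)) {
    if (any(peaks$counts < 0)) stop("counts must be non-negative")
    if (any(peaks$scan < 1L | peaks$scan > length(scan_times)))
      stop("peak scan index outside scan grid")
  }
  peaks <- peaks[order(peaks$scan, peaks$mz), c("scan", "mz", "counts")]
  rownames(peaks) <- NULL
  structure(
    list(peaks = peaks, scan_times = as.numeric(scan_times),
         polarity = polarity, scan_interval = scan_interval),
    class = "SpectrumSeries")
}

#' @export
print.SpectrumSeries <- function(x, ...) {
  cat(sprintf(
    "SpectrumSeries: %d scans (%.1f-%.1f s, interval %.2f s), %s mode, %d peaks, %d total counts\n",
    length(x$scan_times), min(x$scan_times), max(x$scan_times),
    x$scan_interval, x$polarity, nrow(x$peaks), sum(x$peaks$counts)))
  invisible(x)
}

#' Number of scans in a series
#' @param series A `SpectrumSeries`.
#' @export
n_scans <- function(series) length(series$scan_times)

#' Co-add scans into a single spectrum
#'
#' Sums all scan peaks with acquisition time inside `[t_start, t_end]` onto
#' an m/z grid of `bin_width_mda`; per bin the counts are summed and the
#' reported centroid is the counts-weighted mean m/z. Total counts are
#' conserved. An empty time range yields an empty spectrum.
#'
#' @param series A `SpectrumSeries`.
#' @param t_start,t_end Time range in seconds (defaults: whole run).
#' @param bin_width_mda Bin width in mDa (default 5, the screening mass
#'   tolerance scale).
#' @return A `CoaddedSpectrum`: data frame with columns `mz`, `counts`,
#'   sorted by `mz`, with attributes `bin_width_mda` and `time_range`.
#' @export
coadd <- function(series, t_start = -Inf, t_end = Inf, bin_width_mda = 5) {
  stopifnot(inherits(series, "SpectrumSeries"), t_start < t_end,
            bin_width_mda > 0)
  bw <- bin_width_mda / 1000
  times <- series$scan_times[series$peaks$scan]
  sel <- series$peaks[times >= t_start & times <= t_end, ]
  if (nrow(sel) == 0L) {
    out <- data.frame(mz = numeric(0), counts = numeric(0))
  } else {
    bin <- floor(sel$mz / bw)
    counts <- tapply(sel$counts, bin, sum)
    wmz <- tapply(sel$mz * sel$counts, bin, sum) / counts
    # zero-count centroids fall back to the unweighted mean
    zero <- counts == 0
    if (any(zero))
      wmz[zero] <- tapply(sel$mz, bin, mean)[zero]
    out <- data.frame(mz = as.numeric(wmz), counts = as.numeric(counts))
    out <- out[order(out$mz), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("CoaddedSpectrum", "data.frame"),
            bin_width_mda = bin_width_mda,
            time_range = c(t_start, t_end))
}

#' Detect mass peaks in a co-added spectrum
#'
#' Keeps bins with at least `min_counts` counts and merges neighbouring
#' centroids closer than one bin width into a single counts-weighted
#' centroid, so the output is strictly sorted with no two peaks within a
#' bin width of each other.
#'
#' @param spectrum A `CoaddedSpectrum`.
#' @param min_counts Minimum summed counts for a peak (default 1).
#' @return Data frame of ion records: `mz`, `total_counts`,
#'   `classification` (initially `"unclassified"`), sorted by `mz`.
#' @export
detect_mass_peaks <- function(spectrum, min_counts = 1) {
  stopifnot(min_counts >= 1)
  bw <- attr(spectrum, "bin_width_mda") / 1000
  df <- as.data.frame(spectrum)
  df <- df[order(df$mz), ]
  # merge runs of centroids with consecutive gaps < one bin width
  if (nrow(df) > 1L) {
    grp <- cumsum(c(1L, diff(df$mz) >= bw))
    counts <- tapply(df$counts, grp, sum)
    mzw <- tapply(df$mz * df$counts, grp, sum) / counts
    zero <- counts == 0
    if (any(zero)) mzw[zero] <- tapply(df$mz, grp, mean)[zero]
    df <- data.frame(mz = as.numeric(mzw), counts = as.numeric(counts))
  }
  df <- df[df$counts >= min_counts, ]
  out <- data.frame(mz = df$mz, total_counts = df$counts,
                    classification = rep("unclassified", nrow(df)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  out
}

#' Extract an ion profile (XIC)
#'
#' Per-scan summed counts inside a narrow m/z window around a target,
#' across every scan of the run (scans with no matching peak contribute 0).
#'
#' @param series A `SpectrumSeries`.
#' @param target_mz Window centre in Da.
#' @param halfwidth_mda Window half-width in mDa (default 5). Two
#'   co-eluting ions inside one window sum into the same profile.
#' @return An `ExtractionProfile`: list with `target_mz`, `halfwidth_mda`,
#'   `times` (s) and `counts` (one per scan).
#' @export
extract_ion_profile <- function(series, target_mz, halfwidth_mda = 5) {
  stopifnot(inherits(series, "SpectrumSeries"), halfwidth_mda > 0)
  hw <- halfwidth_mda / 1000
  sel <- series$peaks[abs(series$peaks$mz - target_mz) <= hw, ]
  counts <- numeric(n_scans(series))
  if (nrow(sel)) {
    agg <- tapply(sel$counts, sel$scan, sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
  }
  structure(
    list(target_mz = target_mz, halfwidth_mda = halfwidth_mda,
         times = series$scan_times, counts = counts),
    class = "ExtractionProfile")
}

#' @export
print.ExtractionProfile <- function(x, ...) {
  cat(sprintf("ExtractionProfile: m/z %.4f +/- %g mDa, %d scans, %d counts\n",
              x$target_mz, x$halfwidth_mda, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
plot.ExtractionProfile <- function(x, ...) {
  plot(x$times, x$counts, type = "h",
       xlab = "time (s)", ylab = "counts / scan",
       main = sprintf("m/z %.4f (+/- %g mDa)", x$target_mz, x$halfwidth_mda),
       ...)
  invisible(x)
}
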
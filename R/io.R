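# Plain-text run container: one tab-separated table (scan_index, time_s,
# mz, counts) preceded by '#'-prefixed run-level metadata (polarity, scan
# interval, scan count). Everything downstream reads and writes this
# format; reports are tab-separated with a single header line.

#' Write a spectrum series to the columnar run container
#'
#' @param series A `SpectrumSeries`.
#' @param path Output file path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_run <- function(series, path) {
  stopifnot(inherits(series, "SpectrumSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# polarity: %s", series$polarity),
    sprintf("# scan_interval: %.6g", series$scan_interval),
    sprintf("# n_scans: %d", n_scans(series)),
    sprintf("# t0: %.10g", series$scan_times[1]),
    "scan_index\ttime_s\tmz\tcounts"), con)
  df <- data.frame(
    scan_index = series$peaks$scan,
    time_s = sprintf("%.6f", series$scan_times[series$peaks$scan]),
    mz = sprintf("%.6f", series$peaks$mz),
    counts = series$peaks$counts)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spectrum series from the columnar run container
#'
#' @param path File written by [write_run()].
#' @return A `SpectrumSeries`.
#' @export
read_run <- function(path) {
  lines <- readLines(path, n = 10L)
  meta <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit) != 1L) stop("run container missing metadata '", key, "'")
    sub(paste0("^# ", key, ": "), "", hit)
  }
  polarity <- get("polarity")
  dt <- as.numeric(get("scan_interval"))
  n <- as.integer(get("n_scans"))
  t0 <- as.numeric(get("t0"))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spectrum_series(
    data.frame(scan = df$scan_index, mz = df$mz, counts = df$counts),
    scan_times = t0 + (seq_len(n) - 1L) * dt,
    polarity = polarity, scan_interval = dt)
}

#' Write/read a ground-truth table
#'
#' @param truth A `GroundTruth` data frame from [generate_run()].
#' @param path File path (tab-separated text).
#' @return `path` / the truth data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("GroundTruth", "data.frame")
  out
}

#' Write/read a tab-separated report table
#'
#' Used for screening reports, annotation tables, quantitation reports and
#' calibration reference lists.
#'
#' @param report A data frame.
#' @param path File path.
#' @return `path` / the data frame.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
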
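# Poisson-statistics quantitation. Ion counting obeys Poisson statistics,
# so N counts carry a relative error of 1/sqrt(N); the limit of
# quantitation is defined as the analyte amount producing 100 counts
# (10% counting error), derived from the slope of a response curve.

#' Fit a response curve (amount vs. peak area)
#'
#' Least-squares line through the origin by default (a blank-corrected
#' signal of zero at zero amount matches the counting-based LOQ
#' definition); slope is in counts per amount unit. The limit of
#' quantitation is the amount producing `loq_counts` counts.
#'
#' @param points Data frame with columns `amount` (in a consistent unit,
#'   e.g. fmol) and `area` (ion counts, >= 0); at least 2 distinct amounts.
#' @param intercept Fit a free intercept instead of forcing the origin
#'   (default `FALSE`).
#' @param loq_counts Counts defining the LOQ (default 100).
#' @param label Optional compound label.
#' @return A `ResponseCurve`: list with `label`, `points`, `slope`,
#'   `intercept`, `loq`, `loq_counts`.
#' @examples
#' fit_response(data.frame(amount = c(66, 132), area = c(347, 694)))
#' @export
fit_response <- function(points, intercept = FALSE, loq_counts = 100,
                         label = NULL) {
  points <- as.data.frame(points)
  stopifnot(all(c("amount", "area") %in% names(points)))
  if (length(unique(points$amount)) < 2L)
    stop("need at least 2 distinct amounts")
  if (any(points$area < 0)) stop("areas must be non-negative")
  if (all(points$area == 0)) stop("all areas are zero; no response")
  if (intercept) {
    fit <- stats::lm(area ~ amount, data = points)
    b <- unname(stats::coef(fit))
    slope <- b[2]; icpt <- b[1]
  } else {
    slope <- sum(points$amount * points$area) / sum(points$amount^2)
    icpt <- 0
  }
  if (slope <= 0) stop("non-positive response slope")
  structure(
    list(label = label, points = points, slope = slope, intercept = icpt,
         loq = loq_counts / slope, loq_counts = loq_counts),
    class = "ResponseCurve")
}

#' @export
print.ResponseCurve <- function(x, ...) {
  cat(sprintf("ResponseCurve%s: slope %.4g counts/unit, LOQ %.4g (at %d counts), %d points\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$slope, x$loq, x$loq_counts, nrow(x$points)))
  invisible(x)
}

#' Poisson counting relative error
#'
#' For `N` detected ions, `sqrt(N)/N = 1/sqrt(N)`: 100 counts carry a 10%
#' counting error.
#'
#' @param counts Ion counts, > 0.
#' @return Relative error as a fraction.
#' @examples
#' poisson_relative_error(100) # 0.10
#' @export
poisson_relative_error <- function(counts) {
  if (any(counts <= 0)) stop("counts must be positive")
  1 / sqrt(counts)
}

#' Convert observed counts to an amount via a response curve
#'
#' @param counts Observed ion counts (>= 0).
#' @param curve A [fit_response()] result.
#' @return A `QuantEstimate` data frame: `counts`, `amount` (in the
#'   curve's amount unit), `relative_error` (1/sqrt(counts); `NA` at zero
#'   counts, where no counting error is defined).
#' @export
estimate_amount <- function(counts, curve) {
  stopifnot(inherits(curve, "ResponseCurve"))
  if (any(counts < 0)) stop("counts must be non-negative")
  data.frame(
    counts = counts,
    amount = (counts - curve$intercept) / curve$slope,
    relative_error = ifelse(counts > 0, 1 / sqrt(counts), NA_real_))
}

#' Summarise replicate measurements
#'
#' Mean and relative standard deviation across replicate runs.
#'
#' @param values Numeric vector, length >= 2.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List with `mean`, `sd`, `rsd_percent`, `n`.
#' @examples
#' replicate_summary(c(22589, 1352, 2568)) # RSD 135%
#' @export
replicate_summary <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(values)
  if (n < 2L) stop("need at least 2 replicates")
  m <- mean(values)
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  list(mean = m, sd = s, rsd_percent = 100 * s / m, n = n)
}
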
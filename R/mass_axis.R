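# TOF mass calibration. TOF physics gives m/z proportional to the square
# of flight time, so the default functional form fits sqrt(m/z) as a
# third-order polynomial of the (abstract, monotone) flight-time axis; a
# direct m/z = poly3(t) form is available as a switch.

#' Fit a third-order-polynomial TOF mass calibration
#'
#' Least-squares fit of `sqrt(m/z)` (default) or `m/z` as a cubic in flight
#' time. At exactly four references the fit interpolates (zero residuals).
#' The fitted polynomial must be strictly increasing on the reference
#' domain (m/z must be monotone in flight time); a violation is recorded in
#' the `monotone` flag and raises a warning.
#'
#' @param references Data frame (or 2-column matrix) with columns
#'   `flight_time` and `mz`; at least 4 rows with distinct flight times.
#' @param form `"sqrt"` (fit `sqrt(m/z) = poly3(t)`) or `"direct"`
#'   (`m/z = poly3(t)`).
#' @return A `CalibrationModel`: list with `coefficients` (c0..c3), `form`,
#'   `domain` (flight-time range), `mz_range`, `residuals_mda` (per
#'   reference, in mDa), `monotone`.
#' @export
fit_tof_calibration <- function(references, form = c("sqrt", "direct")) {
  form <- match.arg(form)
  references <- as.data.frame(references)
  if (!all(c("flight_time", "mz") %in% names(references)))
    names(references)[1:2] <- c("flight_time", "mz")
  t <- references$flight_time
  mz <- references$mz
  if (length(t) < 4L) stop("need at least 4 calibration references")
  if (anyDuplicated(t)) stop("calibration flight times must be distinct")
  y <- if (form == "sqrt") sqrt(mz) else mz
  fit <- stats::lm(y ~ t + I(t^2) + I(t^3))
  coef <- unname(stats::coef(fit))
  model <- structure(
    list(coefficients = coef, form = form,
         domain = range(t), mz_range = range(mz),
         residuals_mda = NULL, monotone = TRUE),
    class = "CalibrationModel")
  pred <- vapply(t, function(ti) apply_calibration(model, ti, warn = FALSE),
                 numeric(1))
  model$residuals_mda <- (pred - mz) * 1000
  # monotone iff derivative positive across the domain
  tg <- seq(model$domain[1], model$domain[2], length.out = 201L)
  deriv <- coef[2] + 2 * coef[3] * tg + 3 * coef[4] * tg^2
  if (any(deriv <= 0)) {
    model$monotone <- FALSE
    warning("fitted calibration polynomial is not strictly increasing on its domain")
  }
  model
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf(
    "CalibrationModel (%s form): domain [%.4g, %.4g], m/z [%.3f, %.3f], RMS residual %.3f mDa%s\n",
    x$form, x$domain[1], x$domain[2], x$mz_range[1], x$mz_range[2],
    sqrt(mean(x$residuals_mda^2)),
    if (x$monotone) "" else " [NON-MONOTONE]"))
  invisible(x)
}

#' Apply a calibration model to a flight time
#'
#' @param model A `CalibrationModel`.
#' @param flight_time Flight time(s) on the calibration axis; values outside
#'   the fitted domain raise a warning (extrapolation).
#' @param warn Emit the out-of-domain warning (default `TRUE`).
#' @return m/z in Da (squared polynomial value under the `"sqrt"` form).
#' @export
apply_calibration <- function(model, flight_time, warn = TRUE) {
  stopifnot(inherits(model, "CalibrationModel"))
  if (warn && any(flight_time < model$domain[1] | flight_time > model$domain[2]))
    warning("flight time outside calibrated domain; extrapolating")
  val <- .poly3(model$coefficients, flight_time)
  if (model$form == "sqrt") {
    if (any(val < 0)) stop("calibration polynomial negative at requested flight time")
    val^2
  } else {
    if (any(val < 0)) stop("calibration gives negative m/z at requested flight time")
    val
  }
}

#' Invert a calibration model
#'
#' Finds the flight time that maps to a given m/z by root search on the
#' (monotone) calibration domain.
#'
#' @param model A `CalibrationModel` with `monotone = TRUE`.
#' @param mz Target m/z in Da, inside the model's calibrated range.
#' @return Flight time.
#' @export
invert_calibration <- function(model, mz) {
  stopifnot(inherits(model, "CalibrationModel"))
  if (!model$monotone) stop("cannot invert a non-monotone calibration")
  vapply(mz, function(m)
    stats::uniroot(function(t) apply_calibration(model, t, warn = FALSE) - m,
                   interval = model$domain, tol = 1e-12)$root,
    numeric(1))
}

#' Define a lock-mass reference
#'
#' A reference compound of known composition co-analysed with the sample;
#' its exact m/z is computed from the formula and ion species, never typed
#' in by hand.
#'
#' @param label Reference name (e.g. `"P321"`).
#' @param formula Neutral molecular formula.
#' @param species Ion species label (see [ion_species_rules()]).
#' @return A `LockMassReference`: list with `label`, `formula`, `species`,
#'   `exact_mz`, `polarity`.
#' @export
lock_mass_reference <- function(label, formula, species) {
  rules <- ion_species_rules("both", include_ammonium = TRUE)
  row <- rules[rules$label == species, ]
  if (nrow(row) != 1L) stop("unknown ion species '", species, "'")
  structure(
    list(label = label, formula = formula, species = species,
         exact_mz = theoretical_mz(formula, species), polarity = row$polarity),
    class = "LockMassReference")
}

#' Built-in lock-mass references
#'
#' The phosphazene standards P321 and P621 (positive mode, protonated) and
#' tetracosenoic acid (negative mode, deprotonated C24H46O2).
#'
#' @param label One of `"P321"`, `"P621"`, `"tetracosenoic"`.
#' @return A [lock_mass_reference()].
#' @export
builtin_lock_mass <- function(label = c("P321", "P621", "tetracosenoic")) {
  label <- match.arg(label)
  switch(label,
    P321 = lock_mass_reference("P321", "C6H18N3O6P3", "[M+H]+"),
    P621 = lock_mass_reference("P621", "C12H18F12N3O6P3", "[M+H]+"),
    tetracosenoic = lock_mass_reference("tetracosenoic acid", "C24H46O2", "[M-H]-"))
}

#' Lock-mass correct a spectrum series
#'
#' Locates the reference ion in the co-added spectrum of the run (nearest
#' centroid within `search_window_mda` of its exact m/z) and rescales every
#' m/z in the series by `exact_mz / observed_mz`. Single-point
#' multiplicative correction: one reference per polarity per run. The
#' applied factor is attached as attribute `lockmass_factor`.
#'
#' @param series A `SpectrumSeries`.
#' @param reference A `LockMassReference`.
#' @param search_window_mda Search half-window in mDa (default 20).
#' @return The corrected `SpectrumSeries`.
#' @export
lock_mass_correct <- function(series, reference, search_window_mda = 20) {
  stopifnot(inherits(series, "SpectrumSeries"),
            inherits(reference, "LockMassReference"))
  spec <- coadd(series)
  peaks <- detect_mass_peaks(spec, min_counts = 1)
  d <- abs(peaks$mz - reference$exact_mz)
  hit <- which(d <= search_window_mda / 1000)
  if (length(hit) == 0L)
    stop(sprintf("lock-mass reference %s (m/z %.4f) not found within +/-%g mDa",
                 reference$label, reference$exact_mz, search_window_mda))
  observed <- peaks$mz[hit[which.min(d[hit])]]
  factor <- reference$exact_mz / observed
  series$peaks$mz <- series$peaks$mz * factor
  attr(series, "lockmass_factor") <- factor
  series
}
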
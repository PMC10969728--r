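#' Spray-drying process yield
#'
#' Percent of fed solids recovered as powder after cyclone separation:
#' `100 * mass_collected / (solid_fraction * sample_total_weight)`.
#' Values above 100% are non-physical (they indicate weighing or sampling
#' artifacts) and produce a warning rather than an error.
#'
#' @param mass_powder_collected grams of powder collected in the cyclone.
#' @param solid_fraction fraction of emulsion mass that is solids, in (0, 1].
#' @param sample_total_weight grams of emulsion fed to the dryer.
#' @return Yield in percent.
#' @export
#' @examples
#' process_yield(7.4, 0.02, 500)  # 74
process_yield <- function(mass_powder_collected, solid_fraction,
                          sample_total_weight) {
  if (any(mass_powder_collected < 0)) {
    stop_relkin("invalid_input", "collected mass must be non-negative")
  }
  if (any(solid_fraction <= 0) || any(solid_fraction > 1)) {
    stop_relkin("invalid_input", "`solid_fraction` must be in (0, 1]")
  }
  denom <- solid_fraction * sample_total_weight
  if (any(denom <= 0)) {
    stop_relkin("invalid_input", "fed solids mass must be positive")
  }
  y <- 100 * mass_powder_collected / denom
  if (any(y > 100)) {
    warn_relkin("nonphysical_percent",
                "process yield above 100% (non-physical)")
  }
  y
}

#' Fit a linear spectrophotometric calibration curve
#'
#' Ordinary least squares of `absorbance = slope * concentration +
#' intercept`, assuming the Beer–Lambert linear regime (the study reads
#' carvacrol-referenced thyme-oil standards at 260 nm).
#'
#' @param concentrations standard concentrations, g/L; >= 2 distinct values.
#' @param absorbances measured absorbances (AU), same length.
#' @param reference_standard label of the reference compound.
#' @return A list of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared` and `reference_standard`.
#' @export
#' @examples
#' fit_calibration(c(0.5, 1, 2, 4), c(1.1, 2.0, 4.1, 7.9))
fit_calibration <- function(concentrations, absorbances,
                            reference_standard = "carvacrol") {
  if (length(concentrations) != length(absorbances)) {
    stop_relkin("invalid_input", "inputs must have equal length")
  }
  if (length(unique(concentrations)) < 2L) {
    stop_relkin("degenerate_design", "need >= 2 distinct concentrations")
  }
  fit <- stats::lm(absorbances ~ concentrations)
  slope <- stats::coef(fit)[["concentrations"]]
  if (slope <= 0) {
    warn_relkin("suspect_calibration", "calibration slope is not positive")
  }
  structure(list(slope = slope,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r_squared = r_squared_about_mean(absorbances,
                                                  stats::fitted(fit)),
                 reference_standard = reference_standard),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A = %.5g * c + %.5g (R^2 = %.4f, ref: %s)\n",
              x$slope, x$intercept, x$r_squared, x$reference_standard))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Converts an absorbance reading to concentration via
#' `(a - intercept) / slope`. Readings below the intercept extrapolate to
#' negative concentrations; these are returned but flagged with a warning.
#'
#' @param a absorbance (AU); vectorized.
#' @param curve a [fit_calibration()] result.
#' @return Concentration in g/L.
#' @export
absorbance_to_concentration <- function(a, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) {
    stop_relkin("undefined_inverse", "calibration slope is zero")
  }
  conc <- (a - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warn_relkin("extrapolation",
                "absorbance below calibration intercept: negative concentration")
  }
  conc
}

#' Encapsulation efficiency
#'
#' Percent of the emulsion's essential-oil mass retained in the spray-dried
#' powder: `100 * oil_in_powder / oil_in_emulsion`. Like [process_yield()],
#' values above 100% warn rather than error.
#'
#' @param oil_in_powder grams of oil recovered from the powder
#'   (solvent-extraction + calibration-curve quantification).
#' @param oil_in_emulsion grams of oil in the feed emulsion; positive.
#' @return Efficiency in percent.
#' @export
#' @examples
#' encapsulation_efficiency(0.744, 1.0)  # 74.4
encapsulation_efficiency <- function(oil_in_powder, oil_in_emulsion) {
  if (any(oil_in_emulsion <= 0)) {
    stop_relkin("invalid_input", "`oil_in_emulsion` must be positive")
  }
  if (any(oil_in_powder < 0)) {
    stop_relkin("invalid_input", "`oil_in_powder` must be non-negative")
  }
  ee <- 100 * oil_in_powder / oil_in_emulsion
  if (any(ee > 100)) {
    warn_relkin("nonphysical_percent",
                "encapsulation efficiency above 100% (non-physical)")
  }
  ee
}
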
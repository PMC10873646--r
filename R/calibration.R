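#' Protein stock concentration from absorbance (Beer-Lambert)
#'
#' @param absorbance absorbance at the fluorophore's peak (AU).
#' @param extinction_coefficient molar extinction coefficient (M^-1 cm^-1).
#' @param path_length_cm cuvette path length (cm).
#' @return list of class `stock_concentration` with the concentration in
#'   micromolar and the inputs.
#' @export
stock_concentration <- function(absorbance, extinction_coefficient,
                                path_length_cm = 1) {
  if (any(c(absorbance, extinction_coefficient, path_length_cm) <= 0))
    stop("absorbance, extinction coefficient and path length must be > 0")
  conc_M <- absorbance / (extinction_coefficient * path_length_cm)
  structure(list(concentration_uM = conc_M * 1e6, absorbance = absorbance,
                 extinction_coefficient = extinction_coefficient,
                 path_length_cm = path_length_cm),
            class = "stock_concentration")
}

#' @export
print.stock_concentration <- function(x, ...) {
  cat(sprintf("Stock concentration: %.4g uM (A = %.3g, eps = %.3g /M/cm, L = %.3g cm)\n",
              x$concentration_uM, x$absorbance, x$extinction_coefficient,
              x$path_length_cm))
  invisible(x)
}

#' Fit the fluorophore concentration-intensity standard curve
#'
#' Ordinary least squares of mean counts/pixel on concentration over a
#' dilution series. The intercept is fitted (it absorbs camera offset and
#' background counts), not forced through the origin.
#'
#' @param dilution_table data.frame with columns `concentration_nM` and
#'   `mean_intensity` (>= 2 distinct concentrations).
#' @return object of class `calibration_curve`: slope (counts/pixel per nM),
#'   intercept, r-squared, number of points, residuals, and the underlying
#'   [stats::lm] fit.
#' @export
fit_standard_curve <- function(dilution_table) {
  stopifnot(is.data.frame(dilution_table),
            all(c("concentration_nM", "mean_intensity") %in%
                  names(dilution_table)))
  if (nrow(dilution_table) < 2 ||
      length(unique(dilution_table$concentration_nM)) < 2)
    stop("need at least 2 distinct concentrations to fit a line")
  fit <- stats::lm(mean_intensity ~ concentration_nM, data = dilution_table)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = nrow(dilution_table),
                 residuals = unname(stats::residuals(fit)),
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: I = %.4g * C + %.4g (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Convert a cell's mean fluorescence to protein concentration
#'
#' Inverts the standard curve: `(intensity - intercept) / slope`. Estimates
#' below zero (read noise on dim cells) are clipped to 0 with a warning.
#'
#' @param mean_intensity per-cell mean counts/pixel (vectorized).
#' @param curve a [fit_standard_curve()] result.
#' @return concentration(s) in nM.
#' @export
estimate_cell_concentration <- function(mean_intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"),
            all(mean_intensity >= 0))
  conc <- (mean_intensity - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning(sum(conc < 0),
            " concentration estimate(s) below 0 clipped to 0")
    conc <- pmax(conc, 0)
  }
  conc
}
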
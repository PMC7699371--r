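# Reference-instrument processing: size-bin counts to mass concentration
# with density/shape-factor correction, ISO 7708 respirable weighting, and
# calibration of the real-time reference against gravimetric samples.

#' ISO 7708 respirable penetration fraction
#'
#' The respirable convention gives the fraction of airborne particles of a
#' given aerodynamic diameter that penetrates to the gas-exchange region of
#' the lung. It is the complementary cumulative log-normal with median
#' 4.25 um and geometric standard deviation 1.5: weight 1 at zero diameter,
#' 0.5 at 4.25 um, and effectively zero above ~15 um.
#'
#' @param d_aero Aerodynamic diameter(s) in um (>= 0).
#' @return Weight(s) in `[0, 1]`, non-increasing in `d_aero`.
#' @examples
#' respirable_weight(c(0, 4.25, 10))
#' @export
respirable_weight <- function(d_aero) {
  if (any(!is.finite(d_aero)) || any(d_aero < 0))
    stopf("'d_aero' must be finite and >= 0")
  w <- 1 - stats::plnorm(d_aero, meanlog = log(4.25), sdlog = log(1.5))
  w[d_aero == 0] <- 1
  w
}

#' Size-bin sample from a particle counter
#'
#' @param bin_mid_diameter Strictly increasing bin mid-point aerodynamic
#'   diameters in um.
#' @param counts Particle counts per bin (>= 0), same length.
#' @param sample_volume Sampled air volume in cm^3 (> 0).
#' @param duration Sampling duration in seconds (default 15).
#' @return An object of class `size_bin_sample`.
#' @export
size_bin_sample <- function(bin_mid_diameter, counts, sample_volume,
                            duration = 15) {
  if (length(bin_mid_diameter) != length(counts))
    stopf("'bin_mid_diameter' and 'counts' must have equal length")
  if (any(diff(bin_mid_diameter) <= 0))
    stopf("'bin_mid_diameter' must be strictly increasing")
  if (any(counts < 0)) stopf("'counts' must be >= 0")
  check_number(sample_volume, "sample_volume", lower = 1e-12)
  structure(list(bin_mid_diameter = bin_mid_diameter, counts = counts,
                 sample_volume = sample_volume, duration = duration),
            class = "size_bin_sample")
}

#' Convert size-bin counts to a mass concentration
#'
#' Per-particle mass is computed from the volume-equivalent diameter
#' \eqn{d_{ve} = d_{ae}\sqrt{\chi \rho_0 / \rho}} (\eqn{\rho_0} = 1 g/cm^3),
#' the standard aerodynamic-to-volume-equivalent conversion for a particle
#' of density \eqn{\rho} and dynamic shape factor \eqn{\chi}, as
#' \eqn{m = \rho (\pi/6) d_{ve}^3}. Bin masses are weighted by the chosen
#' size convention and summed over bins, divided by the sample volume.
#'
#' With diameters in um, density in g/cm^3 and volume in cm^3 the result is
#' directly in ug/m^3 (the 1e-12 g/um^3 and 1e12 ug m^-3 per g cm^-3
#' factors cancel).
#'
#' @param sample A [size_bin_sample()].
#' @param material A [material_properties()] (density, shape factor).
#' @param fraction Size convention: `"pm25"` (indicator d <= 2.5 um),
#'   `"respirable"` ([respirable_weight()]) or `"total"`.
#' @param shape_mode How the shape factor enters: `"diameter"` (default;
#'   through the \eqn{d_{ve}} conversion above) or `"mass"` (per-particle
#'   mass of the aerodynamic sphere divided by \eqn{\chi}).
#' @return Mass concentration in ug/m^3.
#' @examples
#' s <- size_bin_sample(c(0.5, 1, 2.5), c(100, 50, 10), sample_volume = 1000)
#' bins_to_mass(s, material_properties("ARD", 2.6, 1.5), "respirable")
#' @export
bins_to_mass <- function(sample, material,
                         fraction = c("pm25", "respirable", "total"),
                         shape_mode = c("diameter", "mass")) {
  stopifnot(inherits(sample, "size_bin_sample"),
            inherits(material, "material_properties"))
  fraction <- match.arg(fraction)
  shape_mode <- match.arg(shape_mode)
  d <- sample$bin_mid_diameter
  if (length(d) == 0L || sum(sample$counts) == 0) {
    if (length(d) == 0L) warning("empty size bins; returning 0 ug/m^3")
    return(0)
  }
  rho <- material$density
  chi <- material$shape_factor
  m <- if (shape_mode == "diameter") {
    d_ve <- d * sqrt(chi * 1 / rho)
    rho * (pi / 6) * d_ve^3
  } else {
    rho * (pi / 6) * d^3 / chi
  }
  w <- switch(fraction,
              pm25 = as.numeric(d <= 2.5),
              respirable = respirable_weight(d),
              total = rep(1, length(d)))
  sum(sample$counts * m * w) / sample$sample_volume
}

#' Calibrate the real-time reference against gravimetric samples
#'
#' Ordinary least-squares fit of gravimetric concentrations on paired
#' time-averaged reference (APS) concentrations. The fitted line is the
#' correction applied to real-time reference readings so they agree, on
#' average, with the gravimetric gold standard.
#'
#' @param aps_averages Time-averaged reference concentrations (ug/m^3).
#' @param gravimetric Paired gravimetric concentrations (ug/m^3).
#' @return An object of class `reference_calibration` with fields `slope`,
#'   `intercept`, `r_squared` and the underlying `lm` fit.
#' @examples
#' cal <- calibrate_reference(c(100, 500, 1000), c(110, 520, 1050))
#' correct_reference(cal, 750)
#' @export
calibrate_reference <- function(aps_averages, gravimetric) {
  if (length(aps_averages) != length(gravimetric))
    stopf("inputs must be paired (equal length)")
  ok <- complete.cases(aps_averages, gravimetric)
  x <- aps_averages[ok]; y <- gravimetric[ok]
  if (length(x) < 3L) stopf("need at least 3 complete pairs, got %d",
                            length(x))
  if (var(x) == 0) stopf("reference values have zero variance")
  if (var(y) == 0) stopf("gravimetric values have zero variance")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = 1 - sum(resid(fit)^2) / sum((y - mean(y))^2),
                 fit = fit),
            class = "reference_calibration")
}

#' Apply a reference calibration to real-time readings
#'
#' @param calibration A [calibrate_reference()] result.
#' @param readings Real-time reference readings (ug/m^3).
#' @return Corrected concentrations (ug/m^3).
#' @export
correct_reference <- function(calibration, readings) {
  stopifnot(inherits(calibration, "reference_calibration"))
  calibration$intercept + calibration$slope * readings
}

#' @export
print.reference_calibration <- function(x, ...) {
  cat(sprintf(
    "<reference_calibration> slope %.4f, intercept %.2f ug/m3, R^2 %.4f\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Environmental invariance check of the calibrated reference
#'
#' Fits the reference calibration on default-condition experiments, uses it
#' to predict the gravimetric value for experiments run under varied
#' temperature/humidity/pattern, and regresses the observed varied-condition
#' gravimetric values on those predictions. A slope near 1 with high R^2
#' indicates the reference is insensitive to the varied conditions; the
#' slope and R^2 are reported for the analyst to judge.
#'
#' @param default_pairs Data.frame with columns `aps` and `gravimetric`
#'   from default-condition experiments.
#' @param varied_pairs Same structure for varied-condition experiments.
#' @return List with `slope`, `r_squared`, and the default-condition
#'   `calibration`.
#' @export
invariance_check <- function(default_pairs, varied_pairs) {
  need <- c("aps", "gravimetric")
  if (!all(need %in% names(default_pairs)) ||
      !all(need %in% names(varied_pairs)))
    stopf("pairs need columns 'aps' and 'gravimetric'")
  cal <- calibrate_reference(default_pairs$aps, default_pairs$gravimetric)
  expected <- correct_reference(cal, varied_pairs$aps)
  if (var(expected) == 0) stopf("degenerate varied-condition set")
  fit <- lm(varied_pairs$gravimetric ~ expected)
  list(slope = unname(coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       calibration = cal)
}

#' Per-location median concentrations
#'
#' Summarises chamber spatial homogeneity: the median concentration at each
#' sampling location and the max/min ratio of those medians.
#'
#' @param series_by_location Named list (>= 2 entries) of concentration
#'   vectors, one per chamber location.
#' @return List with `medians` (named numeric) and `ratio` (max/min).
#' @export
spatial_medians <- function(series_by_location) {
  if (!is.list(series_by_location) || length(series_by_location) < 2L)
    stopf("need series for at least 2 locations")
  med <- vapply(series_by_location, median, 0, na.rm = TRUE)
  list(medians = med, ratio = max(med) / min(med))
}
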
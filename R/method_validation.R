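#' @title Targeted method-performance calculations
#' @description Internal-standard-normalized standard-addition calibration and
#'   the derived figures of merit: LOD/LOQ from the intercept standard error
#'   and slope, relative recovery, slope-ratio matrix effect, and intra-/
#'   inter-day precision.
#' @name method_validation
NULL

#' Internal-standard-normalized response
#'
#' `(spiked_area - neat_area) / is_area`: the analyte peak area of the spiked
#' sample minus the endogenous (neat) area, divided by the internal-standard
#' area. A negative value (noise at low spike levels) is allowed and returned
#' with a warning.
#'
#' @param spiked_area,neat_area,is_area peak areas; `is_area > 0`.
#' @return normalized response (unitless).
#' @export
normalized_response <- function(spiked_area, neat_area, is_area) {
  if (any(is_area <= 0)) stop("internal-standard area must be > 0")
  r <- (spiked_area - neat_area) / is_area
  if (any(r < 0)) warning("negative normalized response (noise below neat level)")
  r
}

#' Fit a standard-addition calibration curve
#'
#' Ordinary least squares of normalized response on spiked concentration,
#' reporting the slope and intercept with their standard errors and r-squared.
#'
#' @param levels spiked concentrations (mg/kg), at least 3 distinct values.
#' @param responses normalized responses, same length.
#' @return list of class `calibration_curve` with `slope`, `slope_se`,
#'   `intercept`, `intercept_se`, `r2`, `levels`, `responses`.
#' @export
fit_calibration <- function(levels, responses) {
  stopifnot(length(levels) == length(responses))
  if (length(unique(levels)) < 3) stop("need >= 3 distinct calibration levels")
  if (stats::var(levels) == 0) stop("zero level variance")
  fit <- stats::lm(responses ~ levels)
  sm <- suppressWarnings(summary(fit))  # exact fits trigger a spurious warning
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = unname(sm$coefficients[2, 2]),
    intercept_se = unname(sm$coefficients[1, 2]),
    r2 = r2,
    levels = levels, responses = responses
  ), class = "calibration_curve")
}

#' Limits of detection and quantification
#'
#' `LOD = 3.3 * Sa / b` and `LOQ = 10 * Sa / b`, with `Sa` the standard error
#' of the calibration intercept and `b` the slope, so `LOQ / LOD = 10 / 3.3`
#' exactly. Computed from a low-concentration-range standard-addition curve.
#'
#' @param curve a [fit_calibration()] result.
#' @return concentration in mg/kg.
#' @export
lod <- function(curve) {
  if (curve$slope == 0) stop("zero slope")
  3.3 * curve$intercept_se / curve$slope
}

#' @rdname lod
#' @export
loq <- function(curve) {
  if (curve$slope == 0) stop("zero slope")
  10 * curve$intercept_se / curve$slope
}

#' Relative recovery
#'
#' @param measured measured concentration (mg/kg).
#' @param spiked spiked concentration (mg/kg), > 0.
#' @return recovery in percent.
#' @export
recovery <- function(measured, spiked) {
  if (any(spiked <= 0)) stop("spiked concentration must be > 0")
  100 * measured / spiked
}

#' Matrix effect from calibration slopes
#'
#' Signed slope-ratio definition: `100 * (slope_matrix / slope_solvent - 1)`;
#' ion suppression gives a negative percentage. The alternative
#' post-extraction-spike area-ratio definition is available via
#' `definition = "area_ratio"` with areas in place of slopes.
#'
#' @param slope_matrix calibration slope in matrix (or matrix-spike area).
#' @param slope_solvent calibration slope in solvent (or solvent-spike area);
#'   non-zero.
#' @param definition `"slope_ratio"` (default) or `"area_ratio"` (same
#'   arithmetic, different inputs).
#' @return matrix effect in percent (signed).
#' @export
matrix_effect <- function(slope_matrix, slope_solvent,
                          definition = c("slope_ratio", "area_ratio")) {
  match.arg(definition)
  if (slope_solvent == 0) stop("zero solvent slope")
  100 * (slope_matrix / slope_solvent - 1)
}

#' Precision as relative standard deviation
#'
#' `100 * sd / mean` over replicate values. `scheme = "intra"` treats the
#' values as same-day replicates; `scheme = "inter"` pools replicates across
#' days (pass all values from both days).
#'
#' @param replicate_values numeric vector of replicate measurements (>= 2,
#'   positive mean).
#' @param scheme `"intra"` or `"inter"` (documentation of the design; the
#'   pooled RSD arithmetic is identical once all values are supplied).
#' @return RSD in percent.
#' @export
precision <- function(replicate_values, scheme = c("intra", "inter")) {
  match.arg(scheme)
  if (length(replicate_values) < 2) stop("need >= 2 replicates")
  m <- mean(replicate_values)
  if (m <= 0) stop("non-positive mean is non-physical for peak areas")
  100 * stats::sd(replicate_values) / m
}
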
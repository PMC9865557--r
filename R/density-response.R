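# Density-vs-scaling-factor analysis: linear response fit, relative slope,
# density-matched factor and the balanced-factor recommendation.

#' Construct a density scan
#'
#' @param s scaling factors.
#' @param density simulated densities, g/mL.
#' @param sd density uncertainties, g/mL (carried for display; fits are
#'   unweighted).
#' @param kind `"sigma"` (vdW-radius scaling) or `"charge"`.
#' @param rhoExp experimental reference density, g/mL.
#' @param temperature Kelvin.
#' @return a [DensityScan-class].
#' @export
densityScan <- function(s, density, sd = numeric(), kind = "sigma",
                        rhoExp = NA_real_, temperature = 298) {
  new("DensityScan", s = as.numeric(s), density = as.numeric(density),
      sd = as.numeric(sd), kind = kind, rhoExp = rhoExp,
      temperature = temperature)
}

# two-decimal reporting by truncation toward zero, the only convention
# consistent with both printed slope/density pairs of the reference scans
truncate2 <- function(x) trunc(x * 100) / 100

#' Linear density-response fit
#'
#' Ordinary least squares of density on the scaling factor; over narrow scan
#' ranges the bulk density responds linearly to uniform sigma scaling. R^2 is
#' the squared correlation (1 exactly for a two-point scan).
#'
#' @param scan a [DensityScan-class] with at least two distinct factors.
#' @return a [DensityResponseFit-class].
#' @examples
#' sc <- densityScan(c(1.00, 1.03, 1.05), 3.2 - 1.8 * c(1.00, 1.03, 1.05),
#'                   rhoExp = 1.358)
#' linearFit(sc)
#' @export
linearFit <- function(scan) {
  stopifnot(is(scan, "DensityScan"))
  if (length(unique(scan@s)) < 2L)
    stop("degenerate design: need >= 2 distinct scaling factors", call. = FALSE)
  fit <- stats::lm(density ~ s, data = data.frame(s = scan@s,
                                                  density = scan@density))
  b <- unname(stats::coef(fit)[2]); a <- unname(stats::coef(fit)[1])
  r2 <- if (length(scan@s) == 2L) 1 else
    suppressWarnings(stats::cor(scan@s, scan@density))^2
  if (!is.finite(r2)) r2 <- NA_real_
  new("DensityResponseFit", slope = b, intercept = a, rSquared = r2,
      relativeSlope = if (is.finite(scan@rhoExp)) b / scan@rhoExp else NA_real_,
      rhoExp = scan@rhoExp, sRange = range(scan@s))
}

#' Relative density-response slope
#'
#' Slope divided by the experimental density, a dimensionless response
#' coefficient comparable across ionic liquids.
#'
#' @param slope fitted slope, g/mL per unit scaling factor.
#' @param rhoExp experimental density, g/mL, > 0.
#' @param report also return the two-decimal reported value (truncated toward
#'   zero, full precision retained in `value`).
#' @return the ratio, or (with `report = TRUE`) named
#'   `c(value, reported)`.
#' @examples
#' relativeSlope(-1.82, 1.358, report = TRUE)   # reported -1.34
#' @export
relativeSlope <- function(slope, rhoExp, report = FALSE) {
  if (!is.finite(rhoExp) || rhoExp <= 0)
    stop("rhoExp must be positive", call. = FALSE)
  v <- slope / rhoExp
  if (report) c(value = v, reported = truncate2(v)) else v
}

#' Density-matched scaling factor
#'
#' Solves the fitted line for the experimental density:
#' \eqn{s^* = (\rho_{exp} - intercept) / slope}. Warns when the solution lies
#' outside the scanned range (extrapolation) and when the slope sign is
#' anomalous (density increasing with sigma scaling).
#'
#' @param fit a [DensityResponseFit-class].
#' @param rhoExp experimental density, g/mL; defaults to the fit's own.
#' @return s*, the factor at which the fitted line meets the experiment.
#' @export
densityMatchedFactor <- function(fit, rhoExp = fit@rhoExp) {
  stopifnot(is(fit, "DensityResponseFit"))
  if (!is.finite(rhoExp)) stop("no experimental density given", call. = FALSE)
  if (abs(fit@slope) < 1e-12)
    stop("zero slope: no density-matched factor exists", call. = FALSE)
  if (fit@slope > 0)
    warning("positive density-response slope is anomalous for sigma scaling")
  sStar <- (rhoExp - fit@intercept) / fit@slope
  if (length(fit@sRange) == 2L && is.finite(fit@sRange[1]) &&
      (sStar < fit@sRange[1] || sStar > fit@sRange[2]))
    warning(sprintf("density-matched factor %.4f lies outside the scanned range [%g, %g] (extrapolation)",
                    sStar, fit@sRange[1], fit@sRange[2]))
  sStar
}

#' Balanced scaling-factor recommendation
#'
#' Matching the bulk density alone overfits solvent-solvent interactions;
#' the solvation/partition-derived factor errs the other way. The balanced
#' recommendation is the closed interval between the two, with a suggested
#' point one `step` from the density-derived factor toward the
#' solvation-derived one -- factors giving slightly too-large densities are
#' preferred, so the suggestion stays nearer the density end.
#'
#' @param sDensity density-derived factor (e.g. 1.03).
#' @param sSolvation solvation/partition-derived factor (e.g. 1.00).
#' @param step granularity of the recommendation (default 0.01).
#' @return list with `interval` (sorted) and `suggestion`.
#' @examples
#' balancedFactor(1.03, 1.00)   # suggests 1.02
#' @export
balancedFactor <- function(sDensity, sSolvation, step = 0.01) {
  stopifnot(step > 0)
  if (sDensity == sSolvation)
    stop("density- and solvation-derived factors coincide: nothing to balance",
         call. = FALSE)
  interval <- sort(c(sDensity, sSolvation))
  if (step >= abs(sDensity - sSolvation)) {
    warning("step spans the whole interval: suggestion clamped to the midpoint")
    suggestion <- mean(interval)
  } else {
    suggestion <- sDensity + step * sign(sSolvation - sDensity)
  }
  list(interval = interval, suggestion = suggestion)
}

#' Deviation profile of a scan
#'
#' Signed deviations of the simulated densities from the experimental
#' reference, in scan order.
#'
#' @param scan a [DensityScan-class] with `rhoExp` set.
#' @return data.frame (`s`, `deviation` in g/mL).
#' @export
deviationProfile <- function(scan) {
  stopifnot(is(scan, "DensityScan"))
  if (!is.finite(scan@rhoExp))
    stop("scan carries no experimental reference density", call. = FALSE)
  data.frame(s = scan@s, deviation = scan@density - scan@rhoExp)
}
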
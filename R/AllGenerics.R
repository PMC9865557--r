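#' Net charge of a molecule
#'
#' @param object a [FFTopology-class].
#' @param molecule molecule name.
#' @return net charge in e (full-precision sum of atomic charges).
#' @export
setGeneric("netCharge", function(object, molecule) standardGeneric("netCharge"))

#' Uniform charge scaling
#'
#' Multiply all atomic partial charges of the target molecules by a common
#' factor, the standard fixed-charge-force-field surrogate for polarization
#' and charge-transfer screening in ionic liquids.
#'
#' @param object a [FFTopology-class].
#' @param sQ dimensionless scaling factor, 0 < sQ <= 1.5.
#' @param targets molecule role tags to transform (default `"solvent-ion"`:
#'   the ions of the solvent are scaled while solutes keep full charges).
#' @return the transformed topology.
#' @export
setGeneric("scaleCharges",
  function(object, sQ, targets = "solvent-ion") standardGeneric("scaleCharges"))

#' Uniform Lennard-Jones sigma scaling
#'
#' Multiply the LJ collision diameter sigma of every atom type used by the
#' target molecules by a common factor, loosening (s > 1) or tightening
#' (s < 1) the bulk packing. Epsilon, charges, masses and bonded terms are
#' untouched. Cross interactions with unscaled species follow from re-applying
#' the combination rule to the scaled per-type sigma.
#'
#' @param object a [FFTopology-class].
#' @param sSigma dimensionless scaling factor, 0.5 <= sSigma <= 1.5.
#' @param targets molecule role tags whose atom types are transformed.
#' @return the transformed topology.
#' @export
setGeneric("scaleSigma",
  function(object, sSigma, targets = "solvent-ion") standardGeneric("scaleSigma"))

#' Works stored in a work set
#' @param object a [WorkSet-class].
#' @return numeric vector of dimensionless works (kT).
#' @export
setGeneric("works", function(object) standardGeneric("works"))

#' Free-energy value and uncertainty in kcal/mol
#'
#' Converts a dimensionless (kT) estimate to kcal/mol using the estimate's
#' own temperature, \eqn{k_B = 0.0019872041} kcal/mol/K.
#'
#' @param object a [FreeEnergyEstimate-class].
#' @return named numeric `c(value, sd)` in kcal/mol.
#' @export
setGeneric("inKcal", function(object) standardGeneric("inKcal"))

#' @export
#' @rdname works
setGeneric("stage", function(object) standardGeneric("stage"))

#' Temperature accessor (Kelvin)
#' @param object an object carrying a temperature.
#' @return temperature in K.
#' @export
setGeneric("temperatureOf", function(object) standardGeneric("temperatureOf"))

setMethod("works", "WorkSet", function(object) object@works)
setMethod("stage", "WorkSet", function(object) object@stage)
setMethod("temperatureOf", "WorkSet", function(object) object@temperature)
setMethod("temperatureOf", "FreeEnergyEstimate",
          function(object) object@temperature)
setMethod("temperatureOf", "DensityScan", function(object) object@temperature)

setMethod("inKcal", "FreeEnergyEstimate", function(object) {
  f <- kT_kcal(object@temperature)
  c(value = object@deltaA * f, sd = object@sd * f)
})

#' @export
#' @rdname netCharge
setGeneric("moleculeNames", function(object) standardGeneric("moleculeNames"))
setMethod("moleculeNames", "FFTopology", function(object) {
  vapply(object@molecules, function(m) m@name, character(1), USE.NAMES = FALSE)
})

#' Atom-type table accessor
#' @param object a [FFTopology-class].
#' @return data.frame of atom types (`type`, `sigma` nm, `epsilon` kJ/mol, ...).
#' @export
setGeneric("atomTypes", function(object) standardGeneric("atomTypes"))
setMethod("atomTypes", "FFTopology", function(object) object@atomTypes)

#' Molecule accessor
#' @param object a [FFTopology-class].
#' @param molecule molecule name.
#' @return the [MoleculeDef-class].
#' @export
setGeneric("getMolecule", function(object, molecule) standardGeneric("getMolecule"))
setMethod("getMolecule", "FFTopology", function(object, molecule) {
  m <- object@molecules[[molecule]]
  if (is.null(m)) stop(sprintf("unknown molecule '%s'", molecule))
  m
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "FFTopology", function(object) {
  cat(sprintf("FFTopology: %d atom types, %d molecule(s)\n",
              nrow(object@atomTypes), length(object@molecules)))
  for (m in object@molecules)
    cat(sprintf("  %-12s %3d atoms  role=%-11s net charge %+.4f e\n",
                m@name, nrow(m@atoms), m@role, sum(m@atoms$charge)))
  if (length(object@passthrough))
    cat(sprintf("  (+%d passthrough block(s))\n", length(object@passthrough)))
})

setMethod("show", "WorkSet", function(object) {
  cat(sprintf("WorkSet: %d realization(s), stage '%s', T = %g K\n",
              length(object@works), object@stage, object@temperature))
  cat(sprintf("  mean W = %.4f kT, sd = %.4f kT\n",
              mean(object@works), stats::sd(object@works)))
})

setMethod("show", "FreeEnergyEstimate", function(object) {
  kc <- inKcal(object)
  cat(sprintf("FreeEnergyEstimate [%s]: %.4f kT (%.4f kcal/mol)",
              object@estimator, object@deltaA, kc[["value"]]))
  if (!is.na(object@sd))
    cat(sprintf(" +/- %.4f kT (%.4f kcal/mol)", object@sd, kc[["sd"]]))
  cat(sprintf(", n = %d, T = %g K\n", object@nRealizations, object@temperature))
})

setMethod("show", "DensityScan", function(object) {
  cat(sprintf("DensityScan (%s scaling): %d point(s), T = %g K, rho_exp = %s g/mL\n",
              object@kind, length(object@s), object@temperature,
              ifelse(is.na(object@rhoExp), "NA", format(object@rhoExp))))
  print(data.frame(s = object@s, density = object@density,
                   sd = if (length(object@sd)) object@sd else NA))
})

setMethod("show", "DensityResponseFit", function(object) {
  cat(sprintf("DensityResponseFit: slope %.4f g/mL, intercept %.4f g/mL, R^2 = %.6f\n",
              object@slope, object@intercept, object@rSquared))
  if (is.finite(object@relativeSlope))
    cat(sprintf("  relative slope %.4f (reported %.2f)\n",
                object@relativeSlope, truncate2(object@relativeSlope)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (n = %d)\n", object@n))
  cat(sprintf("  MAE %.4f | MSE %+.4f | RMSE %.4f\n",
              object@mae, object@mse, object@rmse))
  cat(sprintf("  tau %s | PI %s | r %s\n",
              format(round(object@tau, 4)), format(round(object@pi, 4)),
              format(round(object@pearsonR, 4))))
  if (length(object@outliers))
    cat("  outliers:", paste(sprintf("|err|>%s: %d", names(object@outliers),
                                     object@outliers), collapse = ", "), "\n")
})

setMethod("show", "DensityObservation", function(object) {
  cat(sprintf("DensityObservation: %.5f +/- %.5f g/mL over %d sweeps\n",
              object@density, object@sd, object@nSweeps))
  cat(sprintf("  acceptance: displacement %.2f, volume %.2f; energy drift %.2e\n",
              object@acceptance[["displacement"]],
              object@acceptance[["volume"]], object@energyDrift))
})

setMethod("show", "ToyParams", function(object) {
  cat(sprintf("ToyParams: %d ion pairs, T = %g K, P = %g bar\n",
              object@nPairs, object@temperature, object@pressure))
  cat(sprintf("  sigma (%.3f, %.3f) nm x %.3f | q %.3f e x %.3f | rc %.2f nm\n",
              object@sigma[1], object@sigma[2], object@sSigma,
              object@q, object@sQ, object@cutoff))
})

setMethod("show", "EspGrid", function(object) {
  cat(sprintf("EspGrid: %d point(s)%s\n", nrow(object@points),
              if (length(object@potential)) " with reference potential" else ""))
})
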
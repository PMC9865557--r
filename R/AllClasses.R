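#' @import methods
NULL

# ---- Topology ---------------------------------------------------------------

#' Molecule definition within a force-field topology
#'
#' One `[ moleculetype ]` entry: the molecule name, its per-atom records
#' (index, atom type, charge in e, mass in amu) and a role tag used to select
#' scaling targets. Bonded sections belonging to the molecule are preserved
#' verbatim in `extra`.
#'
#' @slot name molecule name.
#' @slot nrexcl exclusion number (kept for round-trip; not interpreted).
#' @slot role one of `"solvent-ion"`, `"solute"`, `"other"`.
#' @slot atoms data.frame with columns `nr`, `type`, `resnr`, `residue`,
#'   `atom`, `cgnr`, `charge`, `mass`.
#' @slot extra character vector of verbatim passthrough lines (bonded terms).
#' @export
setClass("MoleculeDef",
  representation(name = "character", nrexcl = "character", role = "character",
                 atoms = "data.frame", extra = "character"),
  prototype(role = "other", extra = character()))

setValidity("MoleculeDef", function(object) {
  a <- object@atoms
  if (!all(c("nr", "type", "charge", "mass") %in% names(a)))
    return("atoms must have nr, type, charge, mass columns")
  if (nrow(a) > 0L) {
    if (!all(diff(a$nr) == 1L))
      return(sprintf("atom indices of '%s' are not contiguous", object@name))
    if (any(!is.finite(a$mass)) || any(a$mass <= 0))
      return(sprintf("non-positive atom mass in molecule '%s'", object@name))
  }
  if (!object@role %in% c("solvent-ion", "solute", "other"))
    return(sprintf("unknown role '%s'", object@role))
  TRUE
})

#' Fixed-charge force-field topology (GROMACS dialect subset)
#'
#' In-memory representation of a topology file restricted to the sections
#' `[ defaults ]`, `[ atomtypes ]`, `[ moleculetype ]`/`[ atoms ]` and
#' `[ molecules ]`. Every other section (bonded terms, `[ system ]`, ...)
#' is carried as an opaque passthrough block and re-emitted verbatim, in the
#' original order, on write.
#'
#' @slot atomTypes data.frame with columns `type`, `atnum`, `mass`, `charge`,
#'   `ptype`, `sigma` (nm), `epsilon` (kJ/mol).
#' @slot molecules list of [MoleculeDef-class] objects, named by molecule.
#' @slot molCounts data.frame (`name`, `count`) from `[ molecules ]`, possibly
#'   empty.
#' @slot defaultsRaw verbatim body lines of `[ defaults ]`.
#' @slot combinationRule integer combination-rule flag from `[ defaults ]`
#'   (2/3 = Lorentz-Berthelot arithmetic/geometric sigma mixing).
#' @slot passthrough named list of verbatim text blocks (header included).
#' @slot preamble verbatim lines before the first section header.
#' @slot layout character vector giving the original section order; tokens
#'   are `"preamble"`, `"defaults"`, `"atomtypes"`, `"molecule:<name>"`,
#'   `"molcounts"`, `"passthrough:<id>"`.
#' @seealso [readTopology()], [writeTopology()], [scaleCharges()],
#'   [scaleSigma()], [netCharge()]
#' @export
setClass("FFTopology",
  representation(atomTypes = "data.frame", molecules = "list",
                 molCounts = "data.frame", defaultsRaw = "character",
                 combinationRule = "integer", passthrough = "list",
                 preamble = "character", layout = "character"))

setValidity("FFTopology", function(object) {
  at <- object@atomTypes
  need <- c("type", "mass", "charge", "ptype", "sigma", "epsilon")
  if (!all(need %in% names(at)))
    return("atomTypes must have type, mass, charge, ptype, sigma, epsilon")
  if (anyDuplicated(at$type))
    return("duplicated atom-type names")
  if (any(!is.finite(at$sigma)) || any(at$sigma <= 0))
    return("sigma must be > 0 for every atom type")
  if (any(!is.finite(at$epsilon)) || any(at$epsilon < 0))
    return("epsilon must be >= 0 for every atom type")
  for (m in object@molecules) {
    bad <- setdiff(unique(m@atoms$type), at$type)
    if (length(bad))
      return(sprintf("molecule '%s' uses undefined atom type(s): %s",
                     m@name, paste(bad, collapse = ", ")))
  }
  TRUE
})

# ---- ESP --------------------------------------------------------------------

#' Electrostatic-potential grid
#'
#' Grid points around a molecule together with (optionally) a reference
#' potential per point, e.g. from an ab initio ESP scan. Internal units are
#' atomic: coordinates in bohr, potential in Hartree/e.
#'
#' @slot points numeric matrix, one row per grid point (bohr).
#' @slot potential reference potential per point (a.u.); length 0 when the
#'   grid carries no reference values (e.g. freshly built shells).
#' @seealso [espFromCharges()], [espRRMSE()], [mkShellGrid()]
#' @export
setClass("EspGrid",
  representation(points = "matrix", potential = "numeric"))

setValidity("EspGrid", function(object) {
  if (ncol(object@points) != 3L) return("points must be an n x 3 matrix")
  if (nrow(object@points) < 1L) return("grid needs at least one point")
  if (any(!is.finite(object@points))) return("non-finite grid coordinate")
  n <- length(object@potential)
  if (n != 0L && n != nrow(object@points))
    return("potential length must match the number of points")
  TRUE
})

#' Point-charge model of a molecule
#'
#' Atom positions (bohr) and atomic partial charges (e), the ingredients of
#' the Coulomb ESP reconstruction used for charge-quality scoring.
#'
#' @slot coords numeric matrix, one row per atom (bohr).
#' @slot charges atomic charges in e.
#' @export
setClass("ChargeModel",
  representation(coords = "matrix", charges = "numeric"))

setValidity("ChargeModel", function(object) {
  if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
  if (nrow(object@coords) != length(object@charges))
    return("coords and charges lengths differ")
  if (any(!is.finite(object@coords)) || any(!is.finite(object@charges)))
    return("non-finite coordinate or charge")
  TRUE
})

# ---- Nonequilibrium works ---------------------------------------------------

#' Set of nonequilibrium works
#'
#' Per-realization dimensionless microscopic works (units of kT) accumulated
#' during fast-growth (solute-creation) switching, tagged by alchemical stage.
#'
#' @slot works dimensionless works, kT.
#' @slot stage `"vdw-coupling"`, `"charging"` or `"total"`.
#' @slot temperature Kelvin.
#' @slot ids realization identifiers, same length as `works`.
#' @seealso [expEstimator()], [bootstrapSD()], [combineStages()]
#' @export
setClass("WorkSet",
  representation(works = "numeric", stage = "character",
                 temperature = "numeric", ids = "character"))

setValidity("WorkSet", function(object) {
  if (length(object@works) < 1L) return("empty work set")
  if (any(!is.finite(object@works))) {
    bad <- object@ids[!is.finite(object@works)]
    return(sprintf("non-finite work for realization(s): %s",
                   paste(bad, collapse = ", ")))
  }
  if (!object@stage %in% c("vdw-coupling", "charging", "total"))
    return(sprintf("unknown stage '%s'", object@stage))
  if (length(object@temperature) != 1L || object@temperature <= 0)
    return("temperature must be a single positive value")
  if (length(object@ids) != length(object@works))
    return("ids and works lengths differ")
  if (anyDuplicated(object@ids)) return("duplicated realization ids")
  TRUE
})

#' Free-energy estimate with bootstrap uncertainty
#'
#' A solvation (or transfer) free-energy difference in dimensionless units
#' (kT) together with its bootstrap standard deviation and the temperature
#' used for conversion to kcal/mol.
#'
#' @slot deltaA free-energy difference in kT.
#' @slot sd bootstrap standard deviation in kT; `NA` when not computed.
#' @slot temperature Kelvin.
#' @slot nRealizations number of work realizations behind the estimate.
#' @slot estimator tag, e.g. `"EXP"`.
#' @seealso [inKcal()], [transferFreeEnergy()]
#' @export
setClass("FreeEnergyEstimate",
  representation(deltaA = "numeric", sd = "numeric", temperature = "numeric",
                 nRealizations = "integer", estimator = "character"),
  prototype(sd = NA_real_, estimator = "EXP"))

setValidity("FreeEnergyEstimate", function(object) {
  if (length(object@deltaA) != 1L || !is.finite(object@deltaA))
    return("deltaA must be a single finite value")
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

# ---- Density response -------------------------------------------------------

#' Density scan over a scaling factor
#'
#' Simulated bulk densities at a series of charge- or sigma-scaling factors,
#' with the experimental reference density they are compared against.
#'
#' @slot s scaling factors (dimensionless).
#' @slot density simulated densities, g/mL.
#' @slot sd density uncertainties, g/mL (display only; fits are unweighted).
#' @slot kind `"charge"` or `"sigma"`.
#' @slot rhoExp experimental reference density, g/mL.
#' @slot temperature Kelvin.
#' @seealso [linearFit()], [deviationProfile()], [densityMatchedFactor()]
#' @export
setClass("DensityScan",
  representation(s = "numeric", density = "numeric", sd = "numeric",
                 kind = "character", rhoExp = "numeric",
                 temperature = "numeric"))

setValidity("DensityScan", function(object) {
  if (length(object@s) != length(object@density))
    return("s and density lengths differ")
  if (length(object@sd) && length(object@sd) != length(object@s))
    return("sd length must match s")
  if (any(object@density <= 0)) return("densities must be > 0")
  if (!object@kind %in% c("charge", "sigma"))
    return("kind must be 'charge' or 'sigma'")
  TRUE
})

#' Linear density-response fit
#'
#' Ordinary least-squares fit of density against the scaling factor:
#' slope (g/mL per unit factor), intercept, R-squared, and the relative slope
#' (slope divided by the experimental density).
#'
#' @slot slope g/mL per unit scaling factor.
#' @slot intercept g/mL.
#' @slot rSquared squared correlation of the fit.
#' @slot relativeSlope slope / rhoExp (dimensionless); `NA` if no reference.
#' @slot rhoExp experimental density carried from the scan, g/mL.
#' @slot sRange range of scanned factors (for extrapolation warnings).
#' @export
setClass("DensityResponseFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", relativeSlope = "numeric",
                 rhoExp = "numeric", sRange = "numeric"))

setValidity("DensityResponseFit", function(object) {
  if (is.finite(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    return("rSquared must lie in [0, 1]")
  TRUE
})

# ---- Quality metrics --------------------------------------------------------

#' Experiment-calculation agreement report
#'
#' Error metrics (MAE, signed MSE, RMSE, in the data's units), ranking and
#' correlation coefficients (Kendall tau-b, Pearlman predictive index,
#' Pearson r) and outlier counts per absolute-deviation threshold.
#'
#' @slot mae mean absolute error.
#' @slot mse mean signed error.
#' @slot rmse root-mean-squared error.
#' @slot tau Kendall rank correlation (tau-b); `NA` when undefined.
#' @slot pi Pearlman predictive index.
#' @slot pearsonR product-moment correlation.
#' @slot outliers named integer vector, count of |calc - expt| > threshold.
#' @slot n number of data points.
#' @seealso [qualityMetrics()]
#' @export
setClass("MetricsReport",
  representation(mae = "numeric", mse = "numeric", rmse = "numeric",
                 tau = "numeric", pi = "numeric", pearsonR = "numeric",
                 outliers = "integer", n = "integer"))

# ---- Toy ionic fluid --------------------------------------------------------

#' Parameters of the toy ionic-fluid Monte-Carlo model
#'
#' A periodic cubic cell of soft-sphere cations and anions (Lennard-Jones +
#' damped-shifted-force Coulomb) sampled in the NPT ensemble by Metropolis
#' Monte Carlo. A desk-scale stand-in for bulk ionic-liquid cells used to
#' exercise the scaling-to-density pipeline.
#'
#' @slot nPairs number of ion pairs (>= 8).
#' @slot sigma per-species LJ sigma, nm (cation, anion).
#' @slot epsilon per-species LJ epsilon, kJ/mol (cation, anion).
#' @slot q charge magnitude, e; species carry +q and -q.
#' @slot mass per-species masses, amu (cation, anion).
#' @slot sQ charge-scaling factor applied multiplicatively to q.
#' @slot sSigma sigma-scaling factor applied multiplicatively to sigma.
#' @slot temperature Kelvin.
#' @slot pressure bar.
#' @slot maxDisp maximum particle displacement, nm.
#' @slot maxLnV maximum ln-volume step.
#' @slot cutoff interaction cutoff, nm; the box edge must stay > 2 cutoff.
#' @slot alpha Coulomb damping parameter, 1/nm.
#' @slot seed RNG seed.
#' @seealso [toyParams()], [runNptMC()], [densityScanToy()]
#' @export
setClass("ToyParams",
  representation(nPairs = "integer", sigma = "numeric", epsilon = "numeric",
                 q = "numeric", mass = "numeric", sQ = "numeric",
                 sSigma = "numeric", temperature = "numeric",
                 pressure = "numeric", maxDisp = "numeric", maxLnV = "numeric",
                 cutoff = "numeric", alpha = "numeric", seed = "integer"))

setValidity("ToyParams", function(object) {
  if (object@nPairs < 8L) return("nPairs must be >= 8")
  if (length(object@sigma) != 2L || any(object@sigma <= 0))
    return("sigma must be two positive values")
  if (length(object@epsilon) != 2L || any(object@epsilon < 0))
    return("epsilon must be two non-negative values")
  if (length(object@mass) != 2L || any(object@mass <= 0))
    return("mass must be two positive values")
  if (object@q < 0) return("q must be >= 0")
  if (object@temperature <= 0 || object@pressure <= 0)
    return("temperature and pressure must be > 0")
  if (object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' Density observable from a toy-fluid run
#'
#' Mean bulk density with a block-averaged uncertainty, plus the per-sweep
#' density trace, move acceptance rates and an energy-bookkeeping drift
#' diagnostic (relative difference between the incrementally accumulated and
#' the recomputed total potential energy).
#'
#' @slot density mean density, g/mL.
#' @slot sd block-averaged standard error of the mean density, g/mL.
#' @slot nSweeps production sweeps used.
#' @slot acceptance named acceptance rates (`displacement`, `volume`).
#' @slot trace per-sweep production densities, g/mL.
#' @slot energyDrift relative incremental-vs-recomputed energy mismatch.
#' @export
setClass("DensityObservation",
  representation(density = "numeric", sd = "numeric", nSweeps = "integer",
                 acceptance = "numeric", trace = "numeric",
                 energyDrift = "numeric"))

setValidity("DensityObservation", function(object) {
  if (object@density <= 0) return("density must be > 0")
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})
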
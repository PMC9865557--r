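# Fast-growth free-energy analysis: exponential averaging (Jarzynski) over
# dimensionless nonequilibrium works, bootstrap uncertainties, stage
# composition and water -> ionic-liquid transfer free energies.
#
# Sign convention: works are accumulated along the solute-creation
# (decoupled -> coupled) transformation, so the EXP estimate is the solvation
# free energy directly; nothing downstream flips signs.

#' Construct a work set
#'
#' @param works dimensionless microscopic works, units of kT.
#' @param stage `"vdw-coupling"`, `"charging"` or `"total"`.
#' @param temperature Kelvin (used only for kcal/mol conversion of results).
#' @param ids realization identifiers (default `"r1"`, `"r2"`, ...).
#' @return a [WorkSet-class].
#' @export
workSet <- function(works, stage = "total", temperature = 298,
                    ids = paste0("r", seq_along(works))) {
  new("WorkSet", works = as.numeric(works), stage = stage,
      temperature = temperature, ids = as.character(ids))
}

#' Work from a lambda series by trapezoidal quadrature
#'
#' Integrates dH/dlambda over the recorded alchemical schedule,
#' \eqn{W = \int_0^1 (dH/d\lambda)\, d\lambda}, and returns the dimensionless
#' work in kT. The schedule must be non-decreasing and span [0, 1].
#'
#' @param lambda alchemical order parameter, non-decreasing, first 0 and last
#'   1 (within 1e-9).
#' @param dhdl dH/dlambda samples, same length.
#' @param units units of `dhdl`: already-dimensionless `"kT"` or `"kJ/mol"`
#'   (converted using `temperature`).
#' @param temperature Kelvin, needed for the kJ/mol conversion.
#' @return work in kT.
#' @examples
#' integrateDhdl(c(0, 0.5, 1), c(0, 4, 0))   # 2
#' @export
integrateDhdl <- function(lambda, dhdl, units = c("kT", "kJ/mol"),
                          temperature = 298) {
  units <- match.arg(units)
  stopifnot(length(lambda) == length(dhdl), length(lambda) >= 2L)
  if (any(diff(lambda) < 0))
    stop("lambda schedule decreases: not a valid switching path", call. = FALSE)
  if (abs(lambda[1]) > 1e-9 || abs(lambda[length(lambda)] - 1) > 1e-9)
    stop("lambda schedule must start at 0 and end at 1", call. = FALSE)
  w <- pracma::trapz(lambda, dhdl)
  if (units == "kJ/mol") w <- w / (.kB_kJ * temperature)
  w
}

# log(mean(exp(x))) with overflow-safe shift
.logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski exponential-averaging (EXP) estimator
#'
#' \deqn{\Delta A = -\ln \langle e^{-W} \rangle}
#' over the dimensionless works, evaluated with log-sum-exp stabilisation so
#' that works anywhere in roughly [-1e3, 1e3] kT cannot overflow. Exact for a
#' single realization (\eqn{\Delta A = W_1}). The estimator is asymptotically
#' unbiased but overestimates the free energy at finite n.
#'
#' @param workset a [WorkSet-class].
#' @param bootstrap number of bootstrap resamples for the uncertainty; 0
#'   skips it (the estimate's `sd` is then `NA`).
#' @param seed RNG seed for the bootstrap.
#' @return a [FreeEnergyEstimate-class] in kT (kcal/mol via [inKcal()]).
#' @examples
#' ws <- workSet(c(1, 2))
#' expEstimator(ws)   # -log((exp(-1) + exp(-2))/2) ~ 1.3799 kT
#' @export
expEstimator <- function(workset, bootstrap = 0L, seed = 1L) {
  stopifnot(is(workset, "WorkSet"))
  w <- workset@works
  dA <- -.logMeanExp(-w)
  sd <- if (bootstrap > 0L) bootstrapSD(workset, nResamples = bootstrap,
                                        seed = seed) else NA_real_
  new("FreeEnergyEstimate", deltaA = dA, sd = sd,
      temperature = workset@temperature,
      nRealizations = length(w), estimator = "EXP")
}

#' Bootstrap standard deviation of the EXP estimate
#'
#' Resamples the works with replacement (same size), re-applies the EXP
#' estimator to each resample and reports the sample standard deviation of
#' the resample estimates. Deterministic for a fixed seed; the works are
#' canonically ordered by realization id before resampling so the result is
#' permutation invariant.
#'
#' @param workset a [WorkSet-class] with at least two realizations.
#' @param nResamples number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @return bootstrap SD in kT.
#' @export
bootstrapSD <- function(workset, nResamples = 1000L, seed = 1L) {
  stopifnot(is(workset, "WorkSet"))
  n <- length(workset@works)
  if (n < 2L)
    stop("bootstrap uncertainty undefined for a single realization",
         call. = FALSE)
  if (nResamples < 100L)
    stop("use at least 100 bootstrap resamples", call. = FALSE)
  w <- workset@works[order(workset@ids)]
  est <- withSeed(seed, {
    vapply(seq_len(nResamples), function(b) {
      -.logMeanExp(-w[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  stats::sd(est)
}

#' Combine vdW-coupling and charging stages
#'
#' The fast-growth protocol creates the solute in two sequential sub-steps
#' per realization: vdW coupling, then charging. `"per-realization"` (the
#' default, matching that protocol) sums the two works of each realization
#' before estimation and returns a `"total"` [WorkSet-class].
#' `"per-stage"` applies EXP to each stage separately and returns a
#' [FreeEnergyEstimate-class] with the stage free energies summed and the
#' bootstrap SDs combined in quadrature.
#'
#' @param vdw [WorkSet-class] of the vdW-coupling stage.
#' @param charging [WorkSet-class] of the charging stage.
#' @param mode `"per-realization"` or `"per-stage"`.
#' @param bootstrap resamples for the per-stage uncertainties.
#' @param seed RNG seed for the bootstraps.
#' @return a [WorkSet-class] (per-realization) or
#'   [FreeEnergyEstimate-class] (per-stage).
#' @export
combineStages <- function(vdw, charging,
                          mode = c("per-realization", "per-stage"),
                          bootstrap = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(vdw, "WorkSet"), is(charging, "WorkSet"))
  if (vdw@temperature != charging@temperature)
    stop("stage temperatures differ", call. = FALSE)
  if (mode == "per-realization") {
    if (!setequal(vdw@ids, charging@ids))
      stop("per-realization pairing failed: realization ids do not match",
           call. = FALSE)
    o1 <- order(vdw@ids); o2 <- order(charging@ids)
    workSet(vdw@works[o1] + charging@works[o2], stage = "total",
            temperature = vdw@temperature, ids = vdw@ids[o1])
  } else {
    e1 <- expEstimator(vdw, bootstrap = bootstrap, seed = seed)
    e2 <- expEstimator(charging, bootstrap = bootstrap, seed = seed + 1L)
    new("FreeEnergyEstimate", deltaA = e1@deltaA + e2@deltaA,
        sd = sqrt(ifelse(is.na(e1@sd), 0, e1@sd^2) +
                  ifelse(is.na(e2@sd), 0, e2@sd^2)),
        temperature = vdw@temperature,
        nRealizations = min(e1@nRealizations, e2@nRealizations),
        estimator = "EXP(per-stage)")
  }
}

#' Water-to-ionic-liquid transfer free energy
#'
#' \eqn{\Delta\Delta G = \Delta G_{solv,IL} - \Delta G_{solv,water}}, the
#' thermodynamics behind the partition coefficient, with the two bootstrap
#' SDs combined in quadrature. Both estimates must share the temperature
#' (the common kT unit).
#'
#' @param il solvation estimate in the ionic liquid.
#' @param water hydration (solvation-in-water) estimate.
#' @return a [FreeEnergyEstimate-class].
#' @export
transferFreeEnergy <- function(il, water) {
  stopifnot(is(il, "FreeEnergyEstimate"), is(water, "FreeEnergyEstimate"))
  if (il@temperature != water@temperature)
    stop("unit mismatch: the two estimates use different temperatures",
         call. = FALSE)
  sd <- if (is.na(il@sd) && is.na(water@sd)) NA_real_ else
    sqrt(ifelse(is.na(il@sd), 0, il@sd^2) + ifelse(is.na(water@sd), 0, water@sd^2))
  new("FreeEnergyEstimate", deltaA = il@deltaA - water@deltaA, sd = sd,
      temperature = il@temperature,
      nRealizations = min(il@nRealizations, water@nRealizations),
      estimator = "transfer")
}

#' Construct a free-energy estimate directly
#'
#' For importing literature or externally computed values (e.g. hydration
#' references) into the transfer arithmetic.
#'
#' @param value free-energy value.
#' @param sd its standard deviation (same units as `value`).
#' @param units `"kT"` or `"kcal/mol"` (converted to kT internally).
#' @param temperature Kelvin.
#' @param n number of underlying realizations (informational).
#' @param estimator tag.
#' @return a [FreeEnergyEstimate-class].
#' @export
freeEnergyEstimate <- function(value, sd = NA_real_, units = c("kT", "kcal/mol"),
                               temperature = 298, n = 1L,
                               estimator = "external") {
  units <- match.arg(units)
  if (units == "kcal/mol") {
    f <- kT_kcal(temperature)
    value <- value / f
    if (!is.na(sd)) sd <- sd / f
  }
  new("FreeEnergyEstimate", deltaA = value, sd = sd,
      temperature = temperature, nRealizations = as.integer(n),
      estimator = estimator)
}
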
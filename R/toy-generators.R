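# Synthetic generators with known truths: Crooks-consistent Gaussian work
# distributions (exact EXP limit = deltaG) and paired datasets with known
# ideal agreement metrics.

#' Generate Crooks-consistent Gaussian works
#'
#' Draws dimensionless works from
#' \eqn{N(\mu = \Delta G + \sigma_w^2/2,\ \sigma_w^2)}. For a Gaussian
#' forward work distribution the fluctuation theorem fixes the mean at
#' \eqn{\Delta G + \sigma_w^2/2}, so the infinite-sample EXP estimate equals
#' `deltaG` exactly -- a known truth for estimator-recovery tests.
#'
#' @param deltaG true free-energy difference, kT.
#' @param sigmaW work standard deviation, kT (>= 0; 0 gives degenerate works
#'   equal to `deltaG`).
#' @param n number of realizations.
#' @param seed RNG seed.
#' @param temperature Kelvin.
#' @param stage stage label for the resulting [WorkSet-class].
#' @return a [WorkSet-class].
#' @examples
#' ws <- generateGaussianWorks(3, 1, 1000, seed = 7)
#' expEstimator(ws)
#' @export
generateGaussianWorks <- function(deltaG, sigmaW, n, seed = 1L,
                                  temperature = 298, stage = "total") {
  stopifnot(sigmaW >= 0, n >= 1L)
  w <- withSeed(seed, stats::rnorm(n, mean = deltaG + sigmaW^2 / 2,
                                   sd = sigmaW))
  workSet(w, stage = stage, temperature = temperature)
}

#' Generate a paired calculation/experiment dataset
#'
#' Experimental values on a fixed grid spanning a typical solvation
#' free-energy range (-12 to 0 kcal/mol); calculated values are the
#' experimental ones plus independent Gaussian noise. At `noiseSd = 0` every
#' agreement metric is exactly perfect (MAE = 0, tau = PI = r = 1).
#'
#' @param n entries (>= 2).
#' @param noiseSd calculation-noise SD, same units as the values.
#' @param seed RNG seed.
#' @return a paired data.frame (see [pairedData()]).
#' @export
generatePairedDataset <- function(n, noiseSd, seed = 1L) {
  stopifnot(n >= 2L, noiseSd >= 0)
  expt <- seq(-12, 0, length.out = n)
  calc <- expt + withSeed(seed, stats::rnorm(n, 0, noiseSd))
  pairedData(sprintf("solute%02d", seq_len(n)), calc, expt)
}
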
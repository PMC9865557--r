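# Physical constants (CODATA-ish values standard in MD codes)
.kB_kcal <- 0.0019872041     # kcal/mol/K
.kB_kJ   <- 0.0083144621     # kJ/mol/K
.f_coul  <- 138.935458       # kJ/mol * nm / e^2, Coulomb prefactor
.bohr_per_angstrom <- 1.889726
.bar_nm3_to_kJmol  <- 0.0602214076   # P[bar] * V[nm^3] -> kJ/mol
.amu_per_nm3_to_g_per_mL <- 1.66053907e-3

#' Thermal energy in kcal/mol
#'
#' Convenience conversion \eqn{k_B T} used to express dimensionless free
#' energies (units of kT) in kcal/mol.
#'
#' @param temperature temperature in Kelvin.
#' @return kT in kcal/mol.
#' @examples
#' kT_kcal(298)   # ~0.5922
#' @export
kT_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB_kcal * temperature
}

# Evaluate expr with a private RNG stream; global .Random.seed is untouched.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
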
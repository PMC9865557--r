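# ESP charge-quality scoring: reconstruct the molecular electrostatic
# potential from point charges and compare with an ab initio reference by
# relative root-mean-squared error. Internal units are atomic (bohr,
# Hartree/e); Angstrom input is converted on ingestion.

#' Construct a point-charge model
#'
#' @param coords n x 3 matrix of atom positions.
#' @param charges atomic charges in e.
#' @param units coordinate units of the input, converted to bohr internally
#'   (1 Angstrom = 1.889726 bohr).
#' @return a [ChargeModel-class].
#' @export
chargeModel <- function(coords, charges, units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  coords <- unname(as.matrix(coords))
  if (units == "angstrom") coords <- coords * .bohr_per_angstrom
  new("ChargeModel", coords = coords, charges = as.numeric(charges))
}

#' Construct an ESP grid
#'
#' @param points n x 3 matrix of grid-point positions.
#' @param potential optional reference potential per point, atomic units.
#' @param units coordinate units of the input.
#' @return an [EspGrid-class].
#' @export
espGrid <- function(points, potential = numeric(), units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  points <- unname(as.matrix(points))
  if (units == "angstrom") points <- points * .bohr_per_angstrom
  new("EspGrid", points = points, potential = as.numeric(potential))
}

#' Electrostatic potential of a point-charge model
#'
#' Coulomb sum \eqn{V(r_k) = \sum_i q_i / |r_k - r_i|} in atomic units at
#' every grid point. Linear in the charges.
#'
#' @param model a [ChargeModel-class].
#' @param grid an [EspGrid-class] (its reference potential, if any, is
#'   ignored here).
#' @param minDist singularity guard: smallest allowed point-atom distance in
#'   bohr.
#' @return numeric vector of potentials (a.u.), one per grid point.
#' @examples
#' m <- chargeModel(rbind(c(0, 0, 0)), 1)
#' g <- espGrid(rbind(c(1, 0, 0)))
#' espFromCharges(m, g)   # 1.0 a.u.
#' @export
espFromCharges <- function(model, grid, minDist = 1e-6) {
  stopifnot(is(model, "ChargeModel"), is(grid, "EspGrid"))
  p <- grid@points; a <- model@coords
  # n_points x n_atoms distance matrix
  d2 <- outer(rowSums(p^2), rowSums(a^2), "+") - 2 * tcrossprod(p, a)
  d <- sqrt(pmax(d2, 0))
  if (any(d < minDist)) {
    bad <- which(d < minDist, arr.ind = TRUE)
    stop(sprintf("grid point(s) %s coincide with atom(s) %s",
                 paste(unique(bad[, 1]), collapse = ", "),
                 paste(unique(bad[, 2]), collapse = ", ")), call. = FALSE)
  }
  as.numeric((1 / d) %*% model@charges)
}

#' ESP relative root-mean-squared error
#'
#' \deqn{RRMSE = \sqrt{ \sum_k (V_{model,k} - V_{ref,k})^2 / \sum_k V_{ref,k}^2 }}
#' the conventional RESP-literature normalisation: the summed squared
#' deviation relative to the summed squared reference potential.
#'
#' @param modelPotential reconstructed potentials (a.u.).
#' @param referencePotential ab initio reference potentials (a.u.), same
#'   length; must not be identically zero.
#' @param percent return the value multiplied by 100.
#' @return dimensionless RRMSE (fraction, or percent if requested).
#' @examples
#' espRRMSE(c(1, 0), c(1, 1))        # sqrt(1/2)
#' espRRMSE(c(1, 0), c(1, 1), percent = TRUE)
#' @export
espRRMSE <- function(modelPotential, referencePotential, percent = FALSE) {
  stopifnot(length(modelPotential) == length(referencePotential),
            length(referencePotential) >= 1L)
  denom <- sum(referencePotential^2)
  if (denom == 0)
    stop("reference potential is identically zero: RRMSE normalization undefined",
         call. = FALSE)
  val <- sqrt(sum((modelPotential - referencePotential)^2) / denom)
  if (percent) 100 * val else val
}

#' Score a charge model against a reference grid
#'
#' Convenience wrapper: reconstructs the ESP from the charges and computes
#' the RRMSE against the grid's reference potential.
#'
#' @inheritParams espFromCharges
#' @param percent report percent instead of a fraction.
#' @return RRMSE.
#' @export
espScore <- function(model, grid, percent = FALSE) {
  if (!length(grid@potential))
    stop("grid carries no reference potential", call. = FALSE)
  espRRMSE(espFromCharges(model, grid), grid@potential, percent = percent)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build Merz-Kollman-style shell grids
#'
#' Quasi-uniform points on unions of scaled van der Waals surfaces: for each
#' shell scale, every atom contributes a Fibonacci-lattice sphere of radius
#' `scale * radius`, randomly rotated per atom (seeded, hence deterministic),
#' and points falling inside any other atom's scaled sphere are pruned.
#'
#' @param coords n x 3 atom coordinates (bohr).
#' @param radii per-atom vdW radii (bohr), > 0.
#' @param shellScales strictly increasing scales, all > 1 (default the
#'   classic 1.4, 1.6, 1.8, 2.0 shells).
#' @param density target point density, points per bohr^2 of shell area.
#' @param seed RNG seed for the per-atom random rotations.
#' @return an [EspGrid-class] without reference potential.
#' @export
mkShellGrid <- function(coords, radii, shellScales = c(1.4, 1.6, 1.8, 2.0),
                        density = 1.0, seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, length(radii) == nrow(coords))
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)
  if (any(shellScales <= 1) || any(diff(shellScales) <= 0))
    stop("shellScales must be strictly increasing and > 1", call. = FALSE)
  nA <- nrow(coords)
  pts <- withSeed(seed, {
    acc <- list()
    for (sc in shellScales) {
      r <- sc * radii
      for (i in seq_len(nA)) {
        n <- max(1L, round(density * 4 * pi * r[i]^2))
        sph <- .fibSphere(n)
        # random rotation: QR of a random matrix gives a Haar-ish rotation
        qr_ <- qr(matrix(stats::rnorm(9), 3))
        rot <- qr.Q(qr_)
        if (det(rot) < 0) rot[, 1] <- -rot[, 1]
        p <- sweep(sph %*% t(rot) * r[i], 2, coords[i, ], "+")
        # prune points strictly inside any atom's scaled sphere
        keep <- rep(TRUE, nrow(p))
        for (j in seq_len(nA)) {
          if (j == i) next
          dj <- sqrt(rowSums(sweep(p, 2, coords[j, ], "-")^2))
          keep <- keep & (dj >= r[j] - 1e-9)
        }
        acc[[length(acc) + 1L]] <- p[keep, , drop = FALSE]
      }
    }
    do.call(rbind, acc)
  })
  if (is.null(pts) || nrow(pts) == 0L)
    stop("shell construction produced no points (pathological radii?)",
         call. = FALSE)
  new("EspGrid", points = pts, potential = numeric())
}
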
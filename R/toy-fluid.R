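# Desk-scale NPT Metropolis Monte Carlo of a periodic ionic soft-sphere
# fluid: Lennard-Jones (Lorentz-Berthelot mixing) plus damped-shifted-force
# (Wolf-type) Coulomb, particle displacement moves and ln-V volume moves.
# A qualitative stand-in for bulk ionic-liquid cells, small enough to run in
# seconds, used to exercise the scaling -> density response pipeline.

#' Construct toy-model parameters
#'
#' Defaults describe the package's reference toy fluid: 32 ion pairs of
#' unequal-size soft spheres with charge magnitude 0.5 e scaled by the
#' near-optimal charge factor 0.8, at 298 K and 1000 bar. The elevated
#' pressure keeps the tiny cell deep in the dense-fluid region, away from
#' gas-liquid coexistence, so the density responds smoothly (and
#' monotonically) to sigma scaling.
#'
#' @param nPairs ion pairs (>= 8).
#' @param sigma per-species LJ sigma in nm (cation, anion).
#' @param epsilon per-species LJ epsilon in kJ/mol.
#' @param q charge magnitude in e (species carry +q, -q).
#' @param mass per-species masses in amu.
#' @param sQ charge-scaling factor.
#' @param sSigma sigma-scaling factor.
#' @param temperature Kelvin.
#' @param pressure bar.
#' @param maxDisp maximum displacement, nm.
#' @param maxLnV maximum ln-volume step.
#' @param cutoff interaction cutoff, nm.
#' @param alpha Coulomb damping, 1/nm.
#' @param seed RNG seed.
#' @return a [ToyParams-class].
#' @export
toyParams <- function(nPairs = 32L, sigma = c(0.34, 0.30),
                      epsilon = c(1.0, 1.0), q = 0.5, mass = c(196, 280),
                      sQ = 0.8, sSigma = 1.0, temperature = 298,
                      pressure = 1000, maxDisp = 0.05, maxLnV = 0.03,
                      cutoff = 0.55, alpha = 3.6, seed = 42L) {
  new("ToyParams", nPairs = as.integer(nPairs), sigma = sigma,
      epsilon = epsilon, q = q, mass = mass, sQ = sQ, sSigma = sSigma,
      temperature = temperature, pressure = pressure, maxDisp = maxDisp,
      maxLnV = maxLnV, cutoff = cutoff, alpha = alpha, seed = as.integer(seed))
}

# pair-model tables: per-pair sigma, epsilon, Coulomb prefactor and the DSF
# shift constants, all fixed for a run
.toyModel <- function(p) {
  N <- 2L * p@nPairs
  sp <- rep(c(1L, 2L), p@nPairs)               # alternating cation/anion
  sig <- p@sigma[sp] * p@sSigma
  eps <- p@epsilon[sp]
  qv <- ifelse(sp == 1L, p@q, -p@q) * p@sQ
  rc <- p@cutoff; a <- p@alpha
  SIG <- outer(sig, sig, "+") / 2              # Lorentz-Berthelot arithmetic
  EPS <- sqrt(outer(eps, eps))
  QQ <- .f_coul * outer(qv, qv)
  shiftE <- pracma::erfc(a * rc) / rc
  shiftF <- pracma::erfc(a * rc) / rc^2 +
    2 * a / sqrt(pi) * exp(-a^2 * rc^2) / rc
  list(N = N, sp = sp, mass = p@mass[sp], qv = qv,
       SIG = SIG, EPS = EPS, QQ = QQ,
       rc = rc, alpha = a, shiftE = shiftE, shiftF = shiftF,
       beta = 1 / (.kB_kJ * p@temperature),
       pv = p@pressure * .bar_nm3_to_kJmol,    # beta*P*V uses this per nm^3
       ideal = all(eps == 0) && all(qv == 0))
}

# pair energies (kJ/mol) for distances r with per-pair sig/eps/qq vectors
.pairU <- function(r, sig, eps, qq, mdl) {
  inC <- r < mdl$rc
  u <- numeric(length(r))
  if (any(inC)) {
    ri <- r[inC]
    sr6 <- (sig[inC] / ri)^6
    u[inC] <- 4 * eps[inC] * (sr6^2 - sr6) +
      qq[inC] * (pracma::erfc(mdl$alpha * ri) / ri - mdl$shiftE +
                 mdl$shiftF * (ri - mdl$rc))
  }
  u
}

# minimum-image distances from particle i to all others
.distTo <- function(coords, i, L) {
  d <- sweep(coords, 2, coords[i, ], "-")
  d <- d - L * round(d / L)
  r <- sqrt(rowSums(d * d))
  r[i] <- Inf
  r
}

# energy of particle i with everything else
.particleU <- function(coords, i, L, mdl) {
  if (mdl$ideal) return(0)
  r <- .distTo(coords, i, L)
  sum(.pairU(r, mdl$SIG[, i], mdl$EPS[, i], mdl$QQ[, i], mdl))
}

# total potential energy by full recomputation
.totalU <- function(coords, L, mdl) {
  if (mdl$ideal) return(0)
  N <- mdl$N
  u <- 0
  for (i in seq_len(N - 1L)) {
    jj <- (i + 1L):N
    d <- sweep(coords[jj, , drop = FALSE], 2, coords[i, ], "-")
    d <- d - L * round(d / L)
    r <- sqrt(rowSums(d * d))
    u <- u + sum(.pairU(r, mdl$SIG[jj, i], mdl$EPS[jj, i], mdl$QQ[jj, i], mdl))
  }
  u
}

# checkerboard lattice start: opposite charges on adjacent sites
.initCoords <- function(mdl, L) {
  N <- mdl$N
  nSide <- 2L
  while (nSide^3 < 2L * N) nSide <- nSide + 1L   # enough sites per parity
  g <- seq(0, L, length.out = nSide + 1L)[seq_len(nSide)]
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  par <- (round(grid[, 1] / (L / nSide)) + round(grid[, 2] / (L / nSide)) +
          round(grid[, 3] / (L / nSide))) %% 2
  even <- grid[par == 0, , drop = FALSE]
  odd <- grid[par == 1, , drop = FALSE]
  coords <- matrix(0, N, 3)
  coords[mdl$sp == 1L, ] <- even[seq_len(sum(mdl$sp == 1L)), ]
  coords[mdl$sp == 2L, ] <- odd[seq_len(sum(mdl$sp == 2L)), ]
  coords
}

#' Run the toy fluid in the NPT ensemble
#'
#' Metropolis Monte Carlo: each sweep attempts one trial displacement per
#' particle and (by default) one ln-V volume move accepted with probability
#' \eqn{\min(1, \exp(-\beta(\Delta U + P\Delta V) + (N+1)\Delta\ln V))}.
#' The potential energy is tracked incrementally across displacement moves
#' and the relative drift against a from-scratch recomputation is reported as
#' a correctness diagnostic. Deterministic for a fixed seed.
#'
#' @param params a [ToyParams-class].
#' @param nEquil equilibration sweeps (discarded).
#' @param nProd production sweeps (>= 10 x nBlocks recommended).
#' @param nBlocks blocks for the block-averaged density uncertainty.
#' @param volumeEvery attempt a volume move every this many sweeps; 0
#'   disables volume moves (fixed box, e.g. for energy-bookkeeping checks).
#' @return a [DensityObservation-class].
#' @examples
#' \donttest{
#' obs <- runNptMC(toyParams(nPairs = 8L), nEquil = 50, nProd = 100)
#' obs
#' }
#' @export
runNptMC <- function(params, nEquil = 400L, nProd = 1500L, nBlocks = 10L,
                     volumeEvery = 1L) {
  stopifnot(is(params, "ToyParams"))
  validObject(params)
  if (nProd < 10L * nBlocks && volumeEvery > 0L)
    warning("fewer than 10 sweeps per block: density SD will be noisy")
  mdl <- .toyModel(params)
  N <- mdl$N
  massTot <- sum(mdl$mass)

  withSeed(params@seed, {
    L <- max(2.05 * mdl$rc, ceiling((2 * N)^(1 / 3)) *
               max(params@sigma) * params@sSigma * 1.05)
    coords <- .initCoords(mdl, L)
    U <- .totalU(coords, L, mdl)
    accD <- 0L; tryD <- 0L; accV <- 0L; tryV <- 0L
    trace <- numeric(nProd)

    for (sweep in seq_len(nEquil + nProd)) {
      ord <- sample.int(N, N, replace = TRUE)
      xi <- matrix(stats::runif(3L * N, -params@maxDisp, params@maxDisp), N, 3L)
      pAcc <- stats::runif(N)
      for (k in seq_len(N)) {
        i <- ord[k]
        uOld <- .particleU(coords, i, L, mdl)
        old <- coords[i, ]
        coords[i, ] <- (old + xi[k, ]) %% L
        uNew <- .particleU(coords, i, L, mdl)
        dU <- uNew - uOld
        tryD <- tryD + 1L
        if (dU <= 0 || pAcc[k] < exp(-mdl$beta * dU)) {
          accD <- accD + 1L
          U <- U + dU
        } else {
          coords[i, ] <- old
        }
      }
      if (volumeEvery > 0L && sweep %% volumeEvery == 0L) {
        tryV <- tryV + 1L
        V <- L^3
        lnVnew <- log(V) + stats::runif(1, -params@maxLnV, params@maxLnV)
        Lnew <- exp(lnVnew / 3)
        if (Lnew < 2 * mdl$rc)
          stop(sprintf(paste0("box edge %.4f nm shrank below twice the cutoff ",
                              "(%.4f nm); reduce the cutoff or the pressure"),
                       Lnew, 2 * mdl$rc), call. = FALSE)
        sc <- Lnew / L
        coordsNew <- coords * sc
        Unew <- .totalU(coordsNew, Lnew, mdl)
        dV <- Lnew^3 - V
        arg <- -mdl$beta * (Unew - U + mdl$pv * dV) +
          (N + 1) * (lnVnew - log(V))
        if (arg >= 0 || stats::runif(1) < exp(arg)) {
          accV <- accV + 1L
          coords <- coordsNew; L <- Lnew; U <- Unew
        }
      }
      if (sweep > nEquil)
        trace[sweep - nEquil] <- massTot / L^3 * .amu_per_nm3_to_g_per_mL
    }

    drift <- abs(U - .totalU(coords, L, mdl)) /
      max(1, abs(.totalU(coords, L, mdl)))
    if (volumeEvery == 0L)
      trace[] <- massTot / L^3 * .amu_per_nm3_to_g_per_mL
    blocks <- split(trace, cut(seq_along(trace), nBlocks, labels = FALSE))
    bm <- vapply(blocks, mean, numeric(1))
    new("DensityObservation",
        density = mean(trace),
        sd = stats::sd(bm) / sqrt(length(bm)),
        nSweeps = as.integer(nProd),
        acceptance = c(displacement = accD / max(1L, tryD),
                       volume = if (tryV > 0L) accV / tryV else NA_real_),
        trace = trace, energyDrift = drift)
  })
}

#' Mean volume of the last run
#'
#' Helper converting a density observation back to the mean cell volume.
#'
#' @param obs a [DensityObservation-class].
#' @param params the [ToyParams-class] that produced it.
#' @return mean volume in nm^3 (from the mean of 1/V-weighted densities the
#'   per-sweep volumes are recovered exactly, so this is the mean of V).
#' @export
meanVolume <- function(obs, params) {
  mdl <- .toyModel(params)
  mean(sum(mdl$mass) * .amu_per_nm3_to_g_per_mL / obs@trace)
}

#' Density scan with the toy fluid
#'
#' Runs [runNptMC()] at each scaling factor (sigma scaling by default) and
#' assembles a [DensityScan-class]. Each factor gets its own derived seed so
#' the scan is deterministic as a whole.
#'
#' @param params base [ToyParams-class].
#' @param sValues at least two scaling factors.
#' @param nEquil,nProd sweeps per run.
#' @param kind `"sigma"` or `"charge"`: which factor the scan varies.
#' @param rhoExp experimental-reference stand-in; defaults to the mean of the
#'   scanned densities.
#' @return a [DensityScan-class].
#' @export
densityScanToy <- function(params, sValues, nEquil = 300L, nProd = 1000L,
                           kind = c("sigma", "charge"), rhoExp = NA_real_) {
  kind <- match.arg(kind)
  if (length(sValues) < 2L)
    stop("need at least two scaling factors for a scan", call. = FALSE)
  dens <- numeric(length(sValues)); sds <- numeric(length(sValues))
  for (i in seq_along(sValues)) {
    p <- params
    if (kind == "sigma") p@sSigma <- sValues[i] else p@sQ <- sValues[i]
    p@seed <- params@seed + 1000L * i
    obs <- runNptMC(p, nEquil = nEquil, nProd = nProd)
    dens[i] <- obs@density; sds[i] <- obs@sd
  }
  if (!is.finite(rhoExp)) rhoExp <- mean(dens)
  densityScan(sValues, dens, sds, kind = kind, rhoExp = rhoExp,
              temperature = params@temperature)
}
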
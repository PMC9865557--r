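# Independent brute-force oracles used to cross-check the package's
# estimators; deliberately naive implementations.

# direct exponential average, no log-sum-exp stabilisation
naiveEXP <- function(w) -log(mean(exp(-w)))

# Kendall tau-b by explicit pair enumeration
bruteTau <- function(x, y) {
  n <- length(x); nc <- 0; nd <- 0; n1 <- 0; n2 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0) n1 <- n1 + 1
    if (dy == 0) n2 <- n2 + 1
    if (dx != 0 && dy != 0) {
      if (dx * dy > 0) nc <- nc + 1 else nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}

# Pearlman PI by explicit pair enumeration
brutePI <- function(calc, expt) {
  n <- length(calc); num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    de <- expt[j] - expt[i]; dc <- calc[j] - calc[i]
    w <- abs(de)
    cij <- if (dc == 0 || de == 0) 0 else if (de / dc > 0) 1 else -1
    num <- num + w * cij
    den <- den + w
  }
  num / den
}

# structural equality of two topologies (numerics to 1e-12 relative)
expect_topo_equal <- function(a, b) {
  expect_identical(moleculeNames(a), moleculeNames(b))
  ta <- atomTypes(a); tb <- atomTypes(b)
  expect_identical(ta$type, tb$type)
  for (col in c("mass", "charge", "sigma", "epsilon"))
    expect_equal(ta[[col]], tb[[col]], tolerance = 1e-12)
  for (nm in moleculeNames(a)) {
    ma <- getMolecule(a, nm); mb <- getMolecule(b, nm)
    expect_identical(ma@role, mb@role)
    expect_identical(ma@atoms$type, mb@atoms$type)
    expect_equal(ma@atoms$charge, mb@atoms$charge, tolerance = 1e-12)
    expect_equal(ma@atoms$mass, mb@atoms$mass, tolerance = 1e-12)
    expect_identical(ma@extra, mb@extra)
  }
  expect_identical(a@molCounts, b@molCounts)
  invisible(TRUE)
}
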
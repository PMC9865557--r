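test_that("lambda-series quadrature recovers known integrals", {
  l <- seq(0, 1, length.out = 11)
  expect_equal(integrateDhdl(l, rep(3.7, 11)), 3.7)
  ld <- seq(0, 1, length.out = 1e4)
  expect_equal(integrateDhdl(ld, 2 * ld), 1, tolerance = 1e-6)
  expect_equal(integrateDhdl(c(0, 0.5, 1), c(0, 4, 0)), 2)
  # kJ/mol input is converted with kB T
  kT <- 0.0083144621 * 298
  expect_equal(integrateDhdl(l, rep(kT, 11), units = "kJ/mol",
                             temperature = 298), 1)
  expect_error(integrateDhdl(c(0, 0.6, 0.4, 1), c(1, 1, 1, 1)), "decreases")
  expect_error(integrateDhdl(c(0.1, 0.5, 1), c(1, 1, 1)), "start at 0")
})

test_that("EXP estimator matches closed forms and stays stable", {
  expect_equal(expEstimator(workSet(rep(2.5, 8)))@deltaA, 2.5)
  expect_equal(expEstimator(workSet(4.2))@deltaA, 4.2)   # n = 1 exact
  expect_equal(expEstimator(workSet(c(1, 2)))@deltaA,
               -log((exp(-1) + exp(-2)) / 2), tolerance = 1e-12)
  # Gaussian works: EXP limit is mu - sigma^2/2
  set.seed(41)
  w <- rnorm(1e5, mean = 5, sd = sqrt(2))
  expect_equal(expEstimator(workSet(w))@deltaA, 4, tolerance = 0.05)
  # extreme works neither overflow nor lose the dominant term
  expect_equal(expEstimator(workSet(c(-1000, -999)))@deltaA,
               naiveEXP(c(-1000, -999) + 1000) - 1000, tolerance = 1e-8)
  expect_true(is.finite(expEstimator(workSet(c(1000, 999)))@deltaA))
  expect_error(workSet(c(1, NA, 3), ids = c("a", "b", "c")), "b")
})

test_that("EXP agrees with a naive oracle and obeys Jensen's bound", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(2:1000, 1)
    w <- rnorm(n, mean = runif(1, -3, 8), sd = runif(1, 0.1, 3))
    ws <- workSet(w)
    est <- expEstimator(ws)@deltaA
    expect_equal(est, naiveEXP(w), tolerance = 1e-8)
    expect_lte(est, mean(w))
    # permutation invariance
    p <- sample(n)
    expect_equal(expEstimator(workSet(w[p]))@deltaA, est, tolerance = 1e-12)
  }
  # equality in Jensen iff degenerate
  expect_equal(expEstimator(workSet(rep(1.3, 50)))@deltaA, 1.3)
})

test_that("EXP overestimates the true free energy at finite sample size", {
  # Crooks-consistent Gaussian works, n = 100, sigma_w = 2 kT: the known
  # finite-sample bias of EXP is positive
  est <- vapply(1:40, function(s)
    expEstimator(generateGaussianWorks(0, 2, 100, seed = s))@deltaA, numeric(1))
  expect_gt(mean(est), 0)
})

test_that("bootstrap SD is deterministic, calibrated and guarded", {
  ws <- workSet(rep(1.7, 20))
  expect_equal(bootstrapSD(ws, 200, seed = 1), 0)
  ws2 <- generateGaussianWorks(2, 1, 200, seed = 3)
  expect_identical(bootstrapSD(ws2, 300, seed = 9), bootstrapSD(ws2, 300, seed = 9))
  expect_error(bootstrapSD(workSet(1.0)), "single realization")
  expect_error(bootstrapSD(ws2, 50), "at least 100")

  # calibration: bootstrap SD tracks the replication SD of the estimator
  set.seed(77)
  reps <- vapply(1:200, function(i) naiveEXP(rnorm(1e3)), numeric(1))
  ws3 <- workSet(withr::with_seed(5, rnorm(1e3)))
  bsd <- bootstrapSD(ws3, 1000, seed = 2)
  expect_lt(abs(bsd - sd(reps)) / sd(reps), 0.25)
})

test_that("stage composition matches the sequential fast-growth protocol", {
  vdw <- workSet(c(3, 4, 5), stage = "vdw-coupling", ids = c("a", "b", "c"))
  chg0 <- workSet(c(0, 0, 0), stage = "charging", ids = c("a", "b", "c"))
  tot <- combineStages(vdw, chg0)
  expect_s4_class(tot, "WorkSet")
  expect_equal(expEstimator(tot)@deltaA, expEstimator(vdw)@deltaA)

  # degenerate stages: both modes give w1 + w2
  v <- workSet(rep(1.5, 4), stage = "vdw-coupling")
  c2 <- workSet(rep(0.7, 4), stage = "charging")
  expect_equal(expEstimator(combineStages(v, c2))@deltaA, 2.2)
  expect_equal(combineStages(v, c2, mode = "per-stage", bootstrap = 0)@deltaA, 2.2)

  # ids are paired by value, not position
  vs <- workSet(c(1, 2), ids = c("a", "b"), stage = "vdw-coupling")
  cs <- workSet(c(10, 20), ids = c("b", "a"), stage = "charging")
  expect_equal(sort(works(combineStages(vs, cs))), c(12, 21))
  expect_error(combineStages(vs, workSet(1:2, ids = c("x", "y"))), "pairing")

  # Gaussian stages, per-stage closed form
  v3 <- generateGaussianWorks(2, 1, 2e4, seed = 21, stage = "vdw-coupling")
  c3 <- generateGaussianWorks(1, 1, 2e4, seed = 22, stage = "charging")
  est <- combineStages(v3, c3, mode = "per-stage", bootstrap = 0)
  expect_equal(est@deltaA, 3, tolerance = 0.06)
})

test_that("transfer free energies subtract with quadrature uncertainties", {
  il <- freeEnergyEstimate(-5.0, 0.3, units = "kcal/mol")
  water <- freeEnergyEstimate(-3.0, 0.4, units = "kcal/mol")
  tr <- transferFreeEnergy(il, water)
  expect_equal(unname(inKcal(tr)["value"]), -2.0, tolerance = 1e-9)
  expect_equal(unname(inKcal(tr)["sd"]), 0.5, tolerance = 1e-9)

  same <- transferFreeEnergy(il, il)
  expect_equal(same@deltaA, 0)
  expect_equal(same@sd, sqrt(2) * il@sd, tolerance = 1e-12)

  zero <- freeEnergyEstimate(0, 0)
  expect_equal(transferFreeEnergy(il, zero)@deltaA, il@deltaA)
  expect_equal(transferFreeEnergy(il, zero)@sd, il@sd)

  cold <- freeEnergyEstimate(-3.0, 0.4, temperature = 280)
  expect_error(transferFreeEnergy(il, cold), "unit mismatch")
})

test_that("work files and lambda series round-trip", {
  ws <- generateGaussianWorks(3, 1, 25, seed = 4)
  f <- withr::local_tempfile(fileext = ".dat")
  writeWorkFile(ws, f)
  ws2 <- readWorkFile(f)
  expect_equal(works(ws2), works(ws), tolerance = 1e-9)
  expect_identical(stage(ws2), "total")
  expect_equal(temperatureOf(ws2), 298)

  # kcal/mol header converts on read
  fk <- withr::local_tempfile(fileext = ".dat")
  kT <- 0.0019872041 * 298
  writeLines(c("# units=kcal/mol temperature=298", sprintf("r1 %.10f", 2 * kT)), fk)
  expect_equal(works(readWorkFile(fk)), 2, tolerance = 1e-9)

  fx <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("@ title \"dhdl\"", "# comment", "0 0", "0.5 4", "1 0"), fx)
  d <- readLambdaSeries(fx)
  expect_equal(integrateDhdl(d$lambda, d$dhdl), 2)
})
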
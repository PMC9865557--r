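test_that("linear fits recover exact and noisy density responses", {
  s <- c(1.00, 1.03, 1.05)
  exact <- densityScan(s, 3.2 - 1.8 * s, rhoExp = 1.358)
  fit <- linearFit(exact)
  expect_equal(fit@slope, -1.8, tolerance = 1e-9)
  expect_equal(fit@intercept, 3.2, tolerance = 1e-9)
  expect_equal(fit@rSquared, 1, tolerance = 1e-9)

  two <- densityScan(c(1.0, 1.05), c(1.40, 1.31))
  expect_equal(linearFit(two)@rSquared, 1)

  set.seed(11)
  s5 <- seq(0.98, 1.06, by = 0.02)
  noisy <- densityScan(s5, 3.2 - 1.8 * s5 + rnorm(5, sd = 0.002))
  expect_equal(linearFit(noisy)@slope, -1.8, tolerance = 0.05 / 1.8)

  flat <- densityScan(c(1, 1, 1), c(1.3, 1.31, 1.29))
  expect_error(linearFit(flat), "degenerate")
})

test_that("relative slopes reproduce the two-decimal reported values", {
  r1 <- relativeSlope(-1.82, 1.358, report = TRUE)
  expect_equal(r1[["value"]], -1.82 / 1.358, tolerance = 1e-12)
  expect_equal(r1[["reported"]], -1.34)
  r2 <- relativeSlope(-1.73, 1.295, report = TRUE)
  expect_equal(r2[["reported"]], -1.33)
  expect_equal(relativeSlope(0, 1.358), 0)
  # homogeneity
  expect_equal(relativeSlope(-1.82 * 3, 1.358 * 3), relativeSlope(-1.82, 1.358))
  expect_error(relativeSlope(-1.8, 0), "positive")
})

test_that("density-matched factor solves the fitted line", {
  rho <- 1.358
  s <- c(1.00, 1.02, 1.04)
  # line with slope -1.8 passing 0.054 g/mL above rho at s = 1.00
  scan <- densityScan(s, (rho + 0.054) - 1.8 * (s - 1.00), rhoExp = rho)
  fit <- linearFit(scan)
  expect_equal(densityMatchedFactor(fit), 1.03, tolerance = 1e-9)

  # closed-form consistency: the factor where the line crosses rho exactly
  scan2 <- densityScan(c(0.98, 1.00, 1.02), 2.0 - 0.5 * c(0.98, 1.00, 1.02),
                       rhoExp = 2.0 - 0.5 * 1.01)
  expect_equal(suppressWarnings(densityMatchedFactor(linearFit(scan2))), 1.01,
               tolerance = 1e-9)

  # intercept equal to rho: boundary at s* = 0, flagged as extrapolation
  scan3 <- densityScan(c(1.0, 1.1), 2.0 - 0.5 * c(1.0, 1.1), rhoExp = 2.0)
  fit3 <- linearFit(scan3)
  expect_warning(s3 <- densityMatchedFactor(fit3), "outside the scanned range")
  expect_equal(s3, 0, tolerance = 1e-9)

  # anomalous positive slope still solves, with a warning
  up <- linearFit(densityScan(c(1.0, 1.05), c(1.30, 1.39), rhoExp = 1.358))
  expect_warning(sUp <- densityMatchedFactor(up), "anomalous")
  expect_gt(sUp, 1.0)

  zero <- linearFit(densityScan(c(1.0, 1.05), c(1.3, 1.3), rhoExp = 1.358))
  expect_error(suppressWarnings(densityMatchedFactor(zero)), "zero slope")
})

test_that("balanced-factor rule steps from the density end toward solvation", {
  bf <- balancedFactor(1.03, 1.00, 0.01)
  expect_equal(bf$interval, c(1.00, 1.03))
  expect_equal(bf$suggestion, 1.02)
  # charge-scaling analogue, other direction
  expect_equal(balancedFactor(0.78, 0.80, 0.01)$suggestion, 0.79)
  expect_error(balancedFactor(1.02, 1.02), "coincide")
  expect_warning(mid <- balancedFactor(1.03, 1.00, 0.05)$suggestion, "midpoint")
  expect_equal(suppressWarnings(balancedFactor(1.03, 1.00, 0.05)$suggestion),
               1.015)
})

test_that("deviation profiles report signed calc - expt densities", {
  scan <- densityScan(c(1.0, 1.03), c(1.358, 1.358), rhoExp = 1.358)
  expect_equal(deviationProfile(scan)$deviation, c(0, 0))
  # the 298 K endpoint checks: simulated 1.350/1.303 vs experiment 1.358/1.295
  s6 <- densityScan(1.03, 1.350, rhoExp = 1.358)
  expect_equal(deviationProfile(s6)$deviation, -0.008, tolerance = 1e-12)
  s8 <- densityScan(1.03, 1.303, rhoExp = 1.295)
  expect_equal(deviationProfile(s8)$deviation, 0.008, tolerance = 1e-12)
})

test_that("density scans round-trip through CSV with metadata", {
  scan <- densityScan(c(1.0, 1.03, 1.05), c(1.41, 1.35, 1.32),
                      sd = c(0.002, 0.002, 0.003), kind = "sigma",
                      rhoExp = 1.358, temperature = 298)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDensityScan(scan, f)
  back <- readDensityScan(f)
  expect_equal(back@s, scan@s)
  expect_equal(back@density, scan@density, tolerance = 1e-7)
  expect_equal(back@rhoExp, 1.358)
  expect_identical(back@kind, "sigma")
  expect_equal(temperatureOf(back), 298)
})
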
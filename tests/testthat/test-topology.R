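test_that("topology parsing extracts atom types, molecules and roles", {
  top <- readTopology(toyTopologyText())
  at <- atomTypes(top)
  expect_equal(nrow(at), 3L)
  expect_equal(at$sigma[at$type == "CA"], 0.35)
  expect_equal(at$epsilon[at$type == "AN"], 0.5)
  expect_identical(moleculeNames(top), c("CAT", "ANI", "SOL"))
  expect_identical(getMolecule(top, "CAT")@role, "solvent-ion")
  expect_identical(getMolecule(top, "SOL")@role, "solute")
  expect_equal(getMolecule(top, "SOL")@atoms$mass, c(60, 60))
  # bonded block preserved with the molecule
  expect_true(any(grepl("bonds", getMolecule(top, "SOL")@extra)))
  # roles argument overrides comment tags
  top2 <- readTopology(toyTopologyText(), roles = c(SOL = "other"))
  expect_identical(getMolecule(top2, "SOL")@role, "other")
})

test_that("minimal two-type topology parses and bad input errors are specific", {
  txt <- c("[ atomtypes ]",
           "A1 1 10.0 0.0 A 0.30 0.20",
           "B1 2 20.0 0.0 A 0.40 0.10",
           "[ moleculetype ]", "M 3", "[ atoms ]",
           "1 A1 1 M X 1 0.5 10.0",
           "2 B1 1 M Y 1 -0.5 20.0")
  top <- readTopology(txt)
  expect_equal(nrow(atomTypes(top)), 2L)
  expect_equal(netCharge(top, "M"), 0)

  bad <- sub("2 B1", "2 xx", txt)
  expect_error(readTopology(bad), "xx")
  malformed <- sub("0.30", "zzz", txt)
  expect_error(readTopology(malformed), "line 2")
})

test_that("write/read round-trip is a structural identity", {
  top <- readTopology(toyTopologyText())
  txt <- writeTopology(top)
  expect_topo_equal(readTopology(txt), top)
  # and via an actual file
  f <- withr::local_tempfile(fileext = ".top")
  writeTopology(top, f)
  expect_topo_equal(readTopology(f, file = TRUE), top)
  # second generation identical too (formatting is canonical and stable)
  expect_identical(writeTopology(readTopology(txt)), txt)
})

test_that("charge scaling is linear, targeted and composable", {
  top <- readTopology(toyTopologyText())
  s <- scaleCharges(top, 0.8)
  expect_equal(netCharge(s, "CAT"), 0.8)
  expect_equal(netCharge(s, "ANI"), -0.8)
  expect_equal(netCharge(s, "SOL"), 0)            # solute untouched
  expect_equal(getMolecule(s, "SOL")@atoms$charge,
               getMolecule(top, "SOL")@atoms$charge)
  # identity and composition
  expect_topo_equal(scaleCharges(top, 1.0), top)
  expect_topo_equal(scaleCharges(scaleCharges(top, 0.9), 0.8),
                    scaleCharges(top, 0.72))
  # vdW and bonded records untouched
  expect_identical(atomTypes(s), atomTypes(top))
  expect_identical(getMolecule(s, "SOL")@extra, getMolecule(top, "SOL")@extra)
  # bounds and explicit no-op policy
  expect_error(scaleCharges(top, 0), "0 < sQ")
  expect_error(scaleCharges(top, 1.6), "0 < sQ")
  expect_error(scaleCharges(top, 0.8, targets = character()), "empty target")
})

test_that("sigma scaling hits target atom types only and guards shared types", {
  top <- readTopology(toyTopologyText())
  s <- scaleSigma(top, 1.03)
  at <- atomTypes(s)
  expect_equal(at$sigma[at$type == "CA"], 0.35 * 1.03)
  expect_equal(at$sigma[at$type == "SO"], 0.33)   # solute type untouched
  expect_equal(at$epsilon, atomTypes(top)$epsilon)
  expect_equal(getMolecule(s, "CAT")@atoms$charge,
               getMolecule(top, "CAT")@atoms$charge)
  expect_topo_equal(scaleSigma(top, 1.0), top)
  expect_error(scaleSigma(top, 0.4), "0.5 <= sSigma")

  # a type shared between solvent and solute must be split first
  shared <- readTopology(sub("^1  SO ", "1  CA ", toyTopologyText()))
  expect_error(scaleSigma(shared, 1.03), "'CA'")
  dup <- duplicateAtomTypes(shared, "solvent-ion")
  expect_true("CA_scl" %in% atomTypes(dup)$type)
  scaled <- scaleSigma(dup, 1.05)
  at2 <- atomTypes(scaled)
  expect_equal(at2$sigma[at2$type == "CA_scl"], 0.35 * 1.05)
  expect_equal(at2$sigma[at2$type == "CA"], 0.35)
})

test_that("charge and sigma scaling commute", {
  top <- readTopology(toyTopologyText())
  a <- scaleSigma(scaleCharges(top, 0.8), 1.03)
  b <- scaleCharges(scaleSigma(top, 1.03), 0.8)
  expect_topo_equal(a, b)
})

test_that("netCharge sums at full precision and rejects unknown molecules", {
  top <- readTopology(toyTopologyText())
  expect_equal(netCharge(top, "ANI"), -1)
  expect_equal(netCharge(scaleCharges(top, 0.8), "ANI"), -0.8)
  expect_error(netCharge(top, "NOPE"), "unknown molecule")
})
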
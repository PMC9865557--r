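test_that("error metrics match their definitions", {
  perf <- pairedData(1:3, c(-2, 0, 3), c(-2, 0, 3))
  expect_equal(unname(errorMetrics(perf)), c(0, 0, 0))

  sym <- pairedData(1:2, c(1, -1), c(0, 0))
  em <- errorMetrics(sym)
  expect_equal(unname(em), c(1, 0, 1))

  d <- pairedData(1:3, c(1, 2, 3), c(0, 0, 0))
  em2 <- errorMetrics(d)
  expect_equal(em2[["mae"]], 2)
  expect_equal(em2[["mse"]], 2)
  expect_equal(em2[["rmse"]], sqrt(14 / 3), tolerance = 1e-12)
})

test_that("Kendall tau handles perfect, reversed and tied cases", {
  up <- pairedData(1:4, c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(kendallTau(up), 1)
  down <- pairedData(1:4, c(4, 3, 2, 1), c(10, 20, 30, 40))
  expect_equal(kendallTau(down), -1)
  mid <- pairedData(1:4, c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(kendallTau(mid), 4 / 6, tolerance = 1e-12)
  tied <- pairedData(1:3, c(1, 1, 1), c(1, 2, 3))
  expect_warning(expect_true(is.na(kendallTau(tied))), "tied")
})

test_that("Pearlman PI matches pairwise enumeration", {
  mono <- pairedData(1:4, c(1, 2, 3, 4), c(0, 1, 5, 9))
  expect_equal(pearlmanPI(mono), 1)
  anti <- pairedData(1:4, c(4, 3, 2, 1), c(0, 1, 5, 9))
  expect_equal(pearlmanPI(anti), -1)
  ex <- pairedData(1:3, c(0, 2, 1), c(0, 1, 3))
  expect_equal(pearlmanPI(ex), 1 / 3, tolerance = 1e-12)
  flat <- pairedData(1:3, c(1, 2, 3), c(5, 5, 5))
  expect_error(pearlmanPI(flat), "weights undefined")
})

test_that("Pearson r covers exact and near-linear cases", {
  lin <- pairedData(1:5, 2 * (1:5) + 1, 1:5)
  expect_equal(pearsonR(lin), 1)
  neg <- pairedData(1:5, -(1:5), 1:5)
  expect_equal(pearsonR(neg), -1)
  ex <- pairedData(1:3, c(1, 2, 3), c(1, 2, 4))
  expect_equal(pearsonR(ex), 0.982, tolerance = 1e-3)
  const <- pairedData(1:3, c(1, 1, 1), c(1, 2, 3))
  expect_warning(expect_true(is.na(pearsonR(const))), "variance")
})

test_that("outlier counts follow the deviation bands", {
  d <- pairedData(1:3, c(0.5, 1.5, 2.5), c(0, 0, 0))
  expect_equal(unname(outlierCounts(d, c(1, 2))), c(2L, 1L))
  expect_equal(unname(outlierCounts(d, 5)), 0L)
  perf <- pairedData(1:3, 1:3, 1:3)
  expect_equal(unname(outlierCounts(perf)), c(0L, 0L))
})

test_that("tau and PI agree with brute-force oracles on random data", {
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(3:20, 1)
    expt <- round(rnorm(n, sd = 3), sample(0:3, 1))
    calc <- round(expt + rnorm(n, sd = 2), sample(0:3, 1))
    if (var(expt) == 0 || var(calc) == 0) next
    d <- pairedData(seq_len(n), calc, expt)
    expect_equal(kendallTau(d), bruteTau(calc, expt), tolerance = 1e-12)
    expect_equal(pearlmanPI(d), brutePI(calc, expt), tolerance = 1e-12)
    em <- errorMetrics(d)
    expect_gte(em[["rmse"]], em[["mae"]])
    expect_gte(em[["mae"]], abs(em[["mse"]]))
  }
})

test_that("ranking metrics are affine invariant and sign-flip antisymmetric", {
  set.seed(23)
  expt <- rnorm(12); calc <- expt + rnorm(12, sd = 0.7)
  d <- pairedData(1:12, calc, expt)
  d2 <- pairedData(1:12, 3 * calc + 5, 3 * expt + 5)
  expect_equal(kendallTau(d2), kendallTau(d), tolerance = 1e-12)
  expect_equal(pearlmanPI(d2), pearlmanPI(d), tolerance = 1e-12)
  expect_equal(pearsonR(d2), pearsonR(d), tolerance = 1e-12)
  dneg <- pairedData(1:12, -calc, expt)
  expect_equal(kendallTau(dneg), -kendallTau(d), tolerance = 1e-12)
  expect_equal(pearlmanPI(dneg), -pearlmanPI(d), tolerance = 1e-12)
  expect_equal(sign(pearlmanPI(d)), sign(kendallTau(d)))
})

test_that("the full report assembles consistently and exports", {
  d <- generatePairedDataset(15, 0.8, seed = 2)
  r <- qualityMetrics(d)
  expect_s4_class(r, "MetricsReport")
  expect_equal(r@mae, errorMetrics(d)[["mae"]])
  expect_equal(r@tau, kendallTau(d))
  df <- metricsAsData(r)
  expect_equal(df$rmse, r@rmse)
  expect_true("outliers_gt_1" %in% names(df))

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  expect_equal(qualityMetrics(readPairedData(f))@rmse, r@rmse, tolerance = 1e-9)
})
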
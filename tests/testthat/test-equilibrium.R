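test_that("areas convert to concentrations under mass balance", {
  sp <- suppressWarnings(speciesFromAreas(10, 0, 50))  # all monomer
  expect_equal(monomerConc(sp), 50)
  expect_equal(dimerConc(sp), 0)

  sp <- speciesFromAreas(5, 5, 40)  # equal mass split; D in dimer units
  expect_equal(monomerConc(sp), 20)
  expect_equal(dimerConc(sp), 10)

  expect_error(speciesFromAreas(0, 0, 50), "zero")
  expect_error(speciesFromAreas(1, 1, -2), "positive")
  expect_warning(speciesFromAreas(c(100, 5), c(0.1, 5), c(50, 40)),
                 "leverage")
})

test_that("noiseless simulated samples round-trip to the generator species", {
  ch <- simulateDilutionSeries(7, logGrid(1, 100, 5))
  sp <- speciesFromChromatograms(ch)
  truth <- simulateEquilibriumSpecies(logGrid(1, 100, 5), 7)
  expect_equal(monomerConc(sp), monomerConc(truth), tolerance = 1e-4)
  expect_equal(dimerConc(sp), dimerConc(truth), tolerance = 1e-4)
})

test_that("the [M]^2 vs [D] slope estimator is exact on model data", {
  # single point: slope through origin is M^2 / D
  one <- speciesConcentrations(M = 7, D = 7)
  expect_equal(kd(fitKdLinear(one)), 7)

  # noiseless series at any K_D is recovered to machine precision
  for (kdTrue in c(0.1, 7, 135, 1e4)) {
    sp <- simulateEquilibriumSpecies(logGrid(0.5, 500, 9), kdTrue)
    expect_equal(kd(fitKdLinear(sp)), kdTrue, tolerance = 1e-12)
    expect_equal(kd(fitKdLinear(sp, throughOrigin = FALSE)), kdTrue,
                 tolerance = 1e-9)
  }

  expect_error(fitKdLinear(speciesConcentrations(M = c(1, 2), D = c(0, 0))),
               "degenerate")
})

test_that("estimated K_D is scale-equivariant", {
  set.seed(7)
  sp <- simulateEquilibriumSpecies(logGrid(1, 100, 8), 7)
  # multiplicative measurement noise applied identically before/after scaling
  eps <- exp(rnorm(8, 0, 0.05))
  a <- speciesConcentrations(M = monomerConc(sp) * eps, D = dimerConc(sp))
  for (s in c(0.1, 10, 1000)) {
    b <- speciesConcentrations(M = s * monomerConc(sp) * eps,
                               D = s * dimerConc(sp))
    expect_equal(kd(fitKdLinear(b)), s * kd(fitKdLinear(a)),
                 tolerance = 1e-9)
  }
})

test_that("nonlinear dimer-fraction fit matches the linearization", {
  for (kdTrue in c(7, 135)) {
    sp <- simulateEquilibriumSpecies(logGrid(1, 1000, 10), kdTrue)
    expect_equal(kd(fitKdNonlinear(sp)), kdTrue, tolerance = 1e-6)
  }

  # noisy series: the two estimators agree within their uncertainties
  ch <- simulateDilutionSeries(7, logGrid(1, 100, 12), noiseCv = 0.05,
                               seed = 7)
  sp <- speciesFromChromatograms(ch)
  lin <- bootstrapKd(sp, nBoot = 500, seed = 7)
  nl <- fitKdNonlinear(sp)
  expect_gt(kd(nl), ci95(lin)[1])
  expect_lt(kd(nl), ci95(lin)[2])
})

test_that("bootstrap CIs are reproducible and collapse on noiseless data", {
  sp <- simulateEquilibriumSpecies(logGrid(1, 100, 8), 7)
  b <- bootstrapKd(sp, nBoot = 200, seed = 1)
  expect_equal(unname(diff(ci95(b))), 0, tolerance = 1e-9)

  chn <- simulateDilutionSeries(7, logGrid(1, 100, 8), noiseCv = 0.1,
                                seed = 2)
  spn <- speciesFromChromatograms(chn)
  b1 <- bootstrapKd(spn, nBoot = 200, seed = 42)
  b2 <- bootstrapKd(spn, nBoot = 200, seed = 42)
  expect_identical(ci95(b1), ci95(b2))

  expect_error(bootstrapKd(speciesConcentrations(M = c(1, 2), D = c(1, 2)),
                           nBoot = 200), "at least 3")
  expect_error(bootstrapKd(spn, nBoot = 50), "at least 100")
})

test_that("raising true K_D lowers the dimer fraction across the series", {
  ct <- logGrid(1, 100, 10)
  fMean <- vapply(c(1, 7, 50, 500), function(k) {
    sp <- simulateEquilibriumSpecies(ct, k)
    mean(2 * dimerConc(sp) / totalConc(sp))
  }, numeric(1))
  expect_true(all(diff(fMean) < 0))
})
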
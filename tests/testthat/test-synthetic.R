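test_that("equilibrium species solve the monomer-dimer quadratic", {
  # at c_total = K_D the closed form reduces to [M] = c/2, [D] = c/4
  sp <- simulateEquilibriumSpecies(7, 7)
  expect_equal(monomerConc(sp), 3.5)
  expect_equal(dimerConc(sp), 1.75)
  expect_equal(3.5^2 / 1.75, 7)

  # near-infinite dissociation: essentially all monomer
  sp <- simulateEquilibriumSpecies(10, 1e9)
  expect_equal(monomerConc(sp), 10, tolerance = 1e-7)
  expect_lt(dimerConc(sp), 1e-6)

  # independent oracle: bisection root of 2M^2/Kd + M - c = 0
  oracleM <- function(c, kd)
    uniroot(function(m) 2 * m^2 / kd + m - c, c(0, c), tol = 1e-12)$root
  m <- oracleM(100, 7)
  sp <- simulateEquilibriumSpecies(100, 7)
  expect_equal(monomerConc(sp), m, tolerance = 1e-9)
  expect_equal(dimerConc(sp), (100 - m) / 2, tolerance = 1e-9)
})

test_that("mass balance and the K_D identity hold across a parameter sweep", {
  set.seed(1)
  for (rep in 1:25) {
    kdTrue <- 10^runif(1, -1, 4)
    ct <- 10^runif(5, -1, 3)
    sp <- simulateEquilibriumSpecies(ct, kdTrue)
    expect_equal(monomerConc(sp) + 2 * dimerConc(sp), ct, tolerance = 1e-12)
    expect_equal(monomerConc(sp)^2 / dimerConc(sp), rep(kdTrue, 5),
                 tolerance = 1e-9)
  }
})

test_that("equilibrium species reject non-positive inputs", {
  expect_error(simulateEquilibriumSpecies(-1, 7), "positive")
  expect_error(simulateEquilibriumSpecies(10, 0), "positive")
})

test_that("dimer mass fraction increases with total concentration", {
  ct <- logGrid(0.1, 1000, 20)
  sp <- simulateEquilibriumSpecies(ct, 7)
  fD <- 2 * dimerConc(sp) / totalConc(sp)
  expect_true(all(diff(fD) > 0))
})

test_that("noise-free simulated areas equal the species mass fractions", {
  ch <- simulateDilutionSeries(7, c(3.5, 7, 50))
  for (i in seq_along(ch)) {
    meta <- chromMetadata(ch[[i]])
    sp <- simulateEquilibriumSpecies(meta$cTotal, 7)
    expect_equal(meta$areaM / meta$areaD,
                 monomerConc(sp) / (2 * dimerConc(sp)), tolerance = 1e-12)
  }
  # at c_total = K_D the two peaks carry equal mass
  meta <- chromMetadata(ch[[2]])
  expect_equal(meta$areaM, meta$areaD, tolerance = 1e-12)
})

test_that("dilution series is reproducible for a fixed seed", {
  a <- simulateDilutionSeries(7, c(1, 10, 100), noiseCv = 0.05, seed = 99)
  b <- simulateDilutionSeries(7, c(1, 10, 100), noiseCv = 0.05, seed = 99)
  for (i in seq_along(a)) {
    expect_identical(signal(a[[i]]), signal(b[[i]]))
    expect_identical(elutionVolume(a[[i]]), elutionVolume(b[[i]]))
  }
})

test_that("simulation config invariants are enforced", {
  expect_error(simulateDilutionSeries(-1, c(1, 10)), "positive")
  expect_error(simulateDilutionSeries(7, c(1, -10)), "positive")
  expect_error(simulateDilutionSeries(7, c(1, 10), monomerCenter = 25,
                                      dimerCenter = 35), "elutes")
  expect_error(simulateDilutionSeries(7, c(1, 10), noiseCv = -0.1),
               "non-negative")
})

test_that("noiseless time courses are exactly linear at the expected v0", {
  S <- c(0.5, 1.1, 5)
  ds <- simulateTimecourse(143, 1.1, 0.09, S, times = c(5, 10, 15, 20))
  enzymeNmol <- 0.09 * 100 * 1e-3
  v0 <- 143 * enzymeNmol * S / (1.1 + S)
  for (i in seq_along(S)) {
    slopes <- unname(diff(ds@product[i, ]) / diff(ds@times))
    expect_equal(slopes, rep(v0[i], 3), tolerance = 1e-12)
  }
  # half-saturation identity at [S] = Km
  expect_equal(ds@product[2, 1] / 5, 143 * enzymeNmol / 2, tolerance = 1e-12)
})

test_that("time-course simulation is reproducible and validated", {
  a <- simulateTimecourse(143, 1.1, 0.09, c(1, 2), noiseSd = 0.5, seed = 3)
  b <- simulateTimecourse(143, 1.1, 0.09, c(1, 2), noiseSd = 0.5, seed = 3)
  expect_identical(a@product, b@product)
  expect_error(simulateTimecourse(143, 1.1, 0.09, c(1, 2),
                                  times = c(5, 5, 10)), "increasing")
  expect_error(simulateTimecourse(0, 1.1, 0.09, 1), "positive")
})
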
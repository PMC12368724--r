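test_that("chromatogram CSV write/read round-trips exactly", {
  ch <- simulateDilutionSeries(7, 40, noiseCv = 0.02, seed = 5)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  writeChromatogram(ch, path)
  back <- readChromatogram(path)
  expect_identical(elutionVolume(back), elutionVolume(ch))
  expect_identical(signal(back), signal(ch))
  expect_equal(chromMetadata(back)$cTotal, 40)
})

test_that("malformed chromatogram files raise distinct errors", {
  expect_error(readChromatogram("no/such/file.csv"), "not found")

  shuffled <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(volume_mL = c(1, 3, 2), signal_AU = c(0, 1, 0)),
            shuffled, row.names = FALSE)
  expect_error(readChromatogram(shuffled), "non-monotone")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("volume_mL,signal_AU", "1,0.1", "two,0.2"), bad)
  expect_error(readChromatogram(bad), "parse failure")

  one <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("volume_mL", "1", "2"), one)
  expect_error(readChromatogram(one), "two columns")
})

test_that("linear-endpoints baseline subtraction is exact on a line and idempotent", {
  v <- seq(15, 45, by = 0.05)
  line <- chromatogram(v, 0.3 + 0.01 * v)
  expect_equal(signal(subtractBaseline(line)), rep(0, length(v)),
               tolerance = 1e-12)

  peak <- chromatogram(v, dnorm(v, 30, 1))
  once <- subtractBaseline(peak)
  expect_equal(signal(once), signal(peak), tolerance = 1e-9)
  twice <- subtractBaseline(once)
  expect_equal(signal(twice), signal(once), tolerance = 1e-12)
})

test_that("baseline correction recovers areas to within 1% of truth", {
  ch <- simulateDilutionSeries(7, c(2, 20), baselineSlope = 0.01)
  for (x in ch) {
    meta <- chromMetadata(x)
    pk <- quantifySpeciesPeaks(subtractBaseline(x))
    expect_equal(peakArea(pk$monomer), meta$trueAreaM,
                 tolerance = 0.01)
    expect_equal(peakArea(pk$dimer), meta$trueAreaD,
                 tolerance = 0.01)
  }
})

test_that("trapezoidal integration of a Gaussian converges to closed form", {
  for (spacing in c(0.1, 0.01)) {
    v <- seq(15, 45, by = spacing)
    ch <- chromatogram(v, dnorm(v, 35, 0.8))
    a <- peakArea(quantifySpeciesPeaks(ch)$monomer)
    tol <- if (spacing <= 0.01) 1e-3 else 5e-3
    expect_equal(a, 1, tolerance = tol)
  }
})

test_that("peak quantification windows behave and validate", {
  v <- seq(15, 45, by = 0.02)
  ch <- chromatogram(v, dnorm(v, 35, 0.8) + dnorm(v, 25, 0.8))
  pk <- quantifySpeciesPeaks(ch)
  expect_equal(peakArea(pk$monomer), 1, tolerance = 1e-3)
  expect_equal(peakApex(pk$monomer), 35, tolerance = 0.05)
  expect_equal(peakApex(pk$dimer), 25, tolerance = 0.05)

  # window over pure baseline integrates to ~0
  flat <- chromatogram(v, rep(0, length(v)))
  expect_equal(peakArea(quantifySpeciesPeaks(flat)$dimer), 0)

  expect_error(quantifySpeciesPeaks(ch, monomerWindow = c(26, 39)),
               "overlap")
  expect_error(quantifySpeciesPeaks(ch, dimerWindow = c(5, 29)),
               "outside")
})

test_that("simulated area ratios survive quantification within noise", {
  ch <- simulateDilutionSeries(7, logGrid(1, 100, 6), noiseCv = 0.01,
                               seed = 11)
  for (x in ch) {
    meta <- chromMetadata(x)
    pk <- quantifySpeciesPeaks(subtractBaseline(x))
    expect_equal(peakArea(pk$monomer) / peakArea(pk$dimer),
                 meta$areaM / meta$areaD, tolerance = 5e-3)
  }
})
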
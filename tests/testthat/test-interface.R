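test_that("PDB reading excludes waters and assigns radii", {
  pep <- readPDBStructure(extdata("synthetic_pentapeptide.pdb"))
  at <- atomTable(pep)
  expect_equal(nrow(at), 30)          # the HOH HETATM is dropped
  expect_false(any(at$resid == "HOH"))
  expect_setequal(unique(at$element), c("C", "N", "O"))
  expect_equal(at$radius[at$element == "N"][1], 1.55)
  expect_equal(at$x[1], 0.0)
  expect_equal(at$y[at$elety == "CA" & at$resno == 1], 0.85)

  dimer <- readPDBStructure(extdata("synthetic_dimer.pdb"))
  expect_setequal(structureChains(dimer), c("A", "B"))
  expect_equal(nrow(atomTable(dimer)), 24)
})

test_that("isolated spheres match the closed-form SASA", {
  for (r in seq(1, 2, by = 0.25)) {
    s <- shrakeRupleySasa(singleAtom(radius = r))
    expect_equal(s$atom$sasa, 4 * pi * (r + 1.4)^2,
                 tolerance = 5e-3)
  }
  # at 960 points the spiral is exact for a full sphere
  s <- shrakeRupleySasa(singleAtom(radius = 1.5))
  expect_equal(s$atom$sasa, 4 * pi * 2.9^2, tolerance = 1e-12)

  # two equal intersecting spheres: each loses a cap of height R - d/2
  # (area 2*pi*R*h), an analytic check on the sampled path
  for (d in c(2.0, 3.0, 4.5)) {
    two <- atomsAt(rbind(c(0, 0, 0), c(d, 0, 0)), radius = 1.5)
    s <- shrakeRupleySasa(two, nPoints = 960)$atom$sasa
    R <- 2.9
    expected <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    expect_equal(s, rep(expected, 2), tolerance = 5e-3)
  }
})

test_that("disjoint atoms are additive; near atoms occlude monotonically", {
  two <- atomsAt(rbind(c(0, 0, 0), c(100, 0, 0)))
  s2 <- shrakeRupleySasa(two)
  expect_equal(sum(s2$atom$sasa), 2 * 4 * pi * 2.9^2, tolerance = 1e-12)

  # adding a nearby atom can only reduce any existing atom's SASA
  base <- shrakeRupleySasa(atomsAt(rbind(c(0, 0, 0), c(3, 0, 0))))$atom$sasa
  more <- shrakeRupleySasa(
    atomsAt(rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 2.5, 0))))$atom$sasa
  expect_true(all(more[1:2] <= base + 1e-12))
  expect_true(all(more >= 0))
})

test_that("pentapeptide SASA matches the independent reference within 2%", {
  pep <- readPDBStructure(extdata("synthetic_pentapeptide.pdb"))
  s <- shrakeRupleySasa(pep, probe = 1.4, nPoints = 960)
  expect_equal(nrow(s$atom), length(.refPentapeptideSasa))
  relErr <- abs(s$atom$sasa - .refPentapeptideSasa) / .refPentapeptideSasa
  expect_lt(max(relErr), 0.02)
  expect_equal(sum(s$atom$sasa), sum(.refPentapeptideSasa),
               tolerance = 1e-3)
  # per-residue sums are consistent with per-atom values
  expect_equal(sum(s$residue$sasa), sum(s$atom$sasa), tolerance = 1e-9)
})

test_that("SASA converges in the number of sphere points", {
  pep <- readPDBStructure(extdata("synthetic_pentapeptide.pdb"))
  s960 <- sum(shrakeRupleySasa(pep, nPoints = 960)$atom$sasa)
  s4000 <- sum(shrakeRupleySasa(pep, nPoints = 4000)$atom$sasa)
  expect_lt(abs(s4000 - s960) / s4000, 0.01)
})

test_that("interface differencing is symmetric on an isologous toy dimer", {
  dimer <- readPDBStructure(extdata("synthetic_dimer.pdb"))
  rep <- interfaceResidues(dimer, "A", "B")
  expect_gt(rep@totalBuriedPerMonomer, 0)
  # mirror-symmetric chains bury identical areas (within 5%)
  tot <- rep@totalBuriedPerChain
  expect_equal(unname(tot["A"]), unname(tot["B"]), tolerance = 0.05)
  # complex SASA cannot exceed the sum of the isolated-chain SASAs
  sumIso <- sum(shrakeRupleySasa(selectChains(dimer, "A"))$atom$sasa) +
    sum(shrakeRupleySasa(selectChains(dimer, "B"))$atom$sasa)
  sCx <- sum(shrakeRupleySasa(dimer)$atom$sasa)
  expect_lte(sCx, sumIso)
  expect_equal(sumIso - sCx, sum(tot), tolerance = 1e-9)
  # relative buried areas are valid percentages
  rt <- interfaceResidueTable(rep)
  expect_true(all(rt$relativeBuried >= 0 & rt$relativeBuried <= 100))
})

test_that("chains far apart yield an empty interface", {
  dimer <- readPDBStructure(extdata("synthetic_dimer.pdb"))
  at <- atomTable(dimer)
  at$x[at$chain == "B"] <- at$x[at$chain == "B"] + 100
  apart <- proteinStructure(at)
  rep <- interfaceResidues(apart, "A", "B")
  expect_equal(rep@nResidues, 0L)
  expect_equal(nrow(interfaceHbonds(rep)), 0)
  expect_error(interfaceResidues(apart, "A", "C"), "not found")
})

test_that("hydrogen bonds are detected by donor/acceptor distance", {
  mk <- function(d) {
    proteinStructure(data.frame(
      chain = c("A", "B"), resno = c(1L, 1L), resid = c("SER", "ALA"),
      elety = c("OG", "O"), element = c("O", "O"),
      x = c(0, d), y = 0, z = 0, radius = 1.52, stringsAsFactors = FALSE))
  }
  expect_equal(nrow(detectHbonds(mk(2.9))), 1)
  expect_equal(nrow(detectHbonds(mk(4.0))), 0)
  expect_error(detectHbonds(mk(2.9), "A", "Z"), "not present")

  # symmetric toy dimer: the ASN ND2 -> ASN OD1 bond appears once per
  # direction
  dimer <- readPDBStructure(extdata("synthetic_dimer.pdb"))
  hb <- detectHbonds(dimer)
  expect_equal(nrow(hb), 2)
  expect_setequal(hb$donorAtom, "ND2")
  expect_setequal(hb$acceptorAtom, "OD1")
  expect_equal(hb$distance, rep(3.452, 2), tolerance = 1e-3)
})

test_that("the fixed polarity scheme classifies the published interface", {
  expect_equal(classifyPolarity("TYR"), "apolar")
  expect_equal(classifyPolarity("ASN"), "polar")
  expect_error(classifyPolarity("XYZ"), "unknown")

  tab <- sfbglyInterfaceTable()
  pol <- classifyPolarity(tab$resid)
  expect_equal(nrow(tab), 30)
  expect_equal(sum(pol == "apolar"), 19)
  expect_equal(round(100 * mean(pol == "apolar")), 63)
})
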
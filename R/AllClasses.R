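#' @import methods
NULL

#' Chromatogram: an elution trace with sample metadata
#'
#' A single size-exclusion chromatography trace: a strictly increasing
#' elution-volume grid (mL) and the matching detector signal (AU), plus a
#' free-form metadata list. The metadata slots used throughout the package
#' are \code{cTotal} (total protein concentration in uM,
#' monomer-equivalent), \code{buffer} (label such as \code{"P100"}),
#' \code{temperature} (degrees C) and \code{sampleId}.
#'
#' @slot volume numeric, elution volume in mL, strictly increasing.
#' @slot signal numeric, detector signal in AU, same length as volume.
#' @slot metadata list of sample annotations.
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(volume = "numeric", signal = "numeric", metadata = "list"),
  prototype(volume = numeric(0), signal = numeric(0), metadata = list())
)

setValidity("Chromatogram", function(object) {
  msg <- character(0)
  if (length(object@volume) != length(object@signal))
    msg <- c(msg, "volume and signal must have the same length")
  if (length(object@volume) > 1 && any(diff(object@volume) <= 0))
    msg <- c(msg, "volume must be strictly increasing")
  if (anyNA(object@volume) || anyNA(object@signal))
    msg <- c(msg, "volume and signal must not contain NA")
  ct <- object@metadata$cTotal
  if (!is.null(ct) && (!is.numeric(ct) || any(ct <= 0)))
    msg <- c(msg, "metadata$cTotal must be positive when present")
  if (length(msg)) msg else TRUE
})

#' Integrated chromatographic peak
#'
#' @slot lo,hi numeric, integration window bounds (mL).
#' @slot apex numeric, elution volume of the window maximum (mL).
#' @slot area numeric, trapezoidal area (AU*mL), non-negative.
#' @exportClass Peak
setClass("Peak",
  representation(lo = "numeric", hi = "numeric", apex = "numeric",
                 area = "numeric")
)

setValidity("Peak", function(object) {
  msg <- character(0)
  if (!(object@lo < object@apex && object@apex < object@hi))
    msg <- c(msg, "apex must lie strictly inside [lo, hi]")
  if (object@area < 0) msg <- c(msg, "area must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Monomer and dimer concentrations under mass balance
#'
#' Parallel vectors of monomer concentration [M] (uM), dimer concentration
#' [D] (uM, dimer-molar units) and total protein concentration (uM,
#' monomer-equivalent). Validity enforces the mass balance
#' [M] + 2[D] = c_total to 1e-9 relative for every sample.
#'
#' @slot M numeric, monomer concentration (uM).
#' @slot D numeric, dimer concentration (uM, moles of dimer).
#' @slot cTotal numeric, total concentration (uM, monomer-equivalent).
#' @slot flagged logical, samples with extreme dimer fraction (<1\% or
#'   >99\%) that carry high leverage in the linearized fit; flagged, never
#'   dropped.
#' @exportClass SpeciesConcentrations
setClass("SpeciesConcentrations",
  representation(M = "numeric", D = "numeric", cTotal = "numeric",
                 flagged = "logical")
)

setValidity("SpeciesConcentrations", function(object) {
  msg <- character(0)
  n <- length(object@M)
  if (length(object@D) != n || length(object@cTotal) != n ||
      length(object@flagged) != n)
    msg <- c(msg, "M, D, cTotal and flagged must have equal length")
  if (any(object@M < 0) || any(object@D < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (n > 0) {
    rel <- abs(object@M + 2 * object@D - object@cTotal) /
      pmax(object@cTotal, .Machine$double.eps)
    if (any(rel > 1e-9))
      msg <- c(msg, "mass balance [M] + 2[D] = c_total violated (>1e-9 relative)")
  }
  if (length(msg)) msg else TRUE
})

#' Dimer dissociation-constant fit
#'
#' @slot kd numeric, estimated K_D (uM).
#' @slot stderr numeric, standard error of kd (uM; NA when unavailable).
#' @slot nPoints integer, number of samples used.
#' @slot rSquared numeric, coefficient of determination against the fitted
#'   line (NA for a single point).
#' @slot method character, one of \code{"linear-origin"},
#'   \code{"linear-free-intercept"}, \code{"nonlinear"}.
#' @slot ci95 numeric(2), percentile bootstrap 95\% CI (uM), NA until
#'   \code{\link{bootstrapKd}} is run.
#' @slot data SpeciesConcentrations used in the fit.
#' @exportClass DimerEquilibriumFit
setClass("DimerEquilibriumFit",
  representation(kd = "numeric", stderr = "numeric", nPoints = "integer",
                 rSquared = "numeric", method = "character",
                 ci95 = "numeric", data = "SpeciesConcentrations")
)

setValidity("DimerEquilibriumFit", function(object) {
  msg <- character(0)
  if (object@kd <= 0) msg <- c(msg, "kd must be positive")
  if (!object@method %in% c("linear-origin", "linear-free-intercept",
                            "nonlinear"))
    msg <- c(msg, "unknown method label")
  if (length(object@ci95) != 2) msg <- c(msg, "ci95 must have length 2")
  if (length(msg)) msg else TRUE
})

#' Enzyme kinetics time-course dataset
#'
#' Product accumulation (nmol) measured over time at several substrate
#' concentrations, with the enzyme concentration and reaction volume needed
#' to convert Vmax into a turnover number.
#'
#' @slot substrate numeric, substrate concentrations (mM).
#' @slot times numeric, sampling times (min), strictly increasing.
#' @slot product matrix, nmol of product; rows = substrate, cols = times.
#' @slot E0 numeric, enzyme concentration in the assay (uM).
#' @slot reactionVolume numeric, assay volume (uL).
#' @exportClass KineticsDataset
setClass("KineticsDataset",
  representation(substrate = "numeric", times = "numeric",
                 product = "matrix", E0 = "numeric",
                 reactionVolume = "numeric")
)

setValidity("KineticsDataset", function(object) {
  msg <- character(0)
  if (nrow(object@product) != length(object@substrate) ||
      ncol(object@product) != length(object@times))
    msg <- c(msg, "product must be a substrate x times matrix")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@product < 0)) msg <- c(msg, "product must be non-negative")
  if (object@E0 <= 0 || object@reactionVolume <= 0)
    msg <- c(msg, "E0 and reactionVolume must be positive")
  if (length(msg)) msg else TRUE
})

#' Michaelis-Menten fit result
#'
#' @slot kcat numeric, turnover number (min^-1).
#' @slot kcatSd numeric, its standard deviation.
#' @slot km numeric, Michaelis constant (mM).
#' @slot kmSd numeric, its standard deviation.
#' @slot efficiency numeric, kcat/Km (min^-1 mM^-1).
#' @slot efficiencySd numeric, propagated sd of the efficiency.
#' @slot vmax numeric, fitted maximal rate (nmol/min).
#' @slot rates data.frame of (S, v0) used in the fit.
#' @exportClass MMFit
setClass("MMFit",
  representation(kcat = "numeric", kcatSd = "numeric", km = "numeric",
                 kmSd = "numeric", efficiency = "numeric",
                 efficiencySd = "numeric", vmax = "numeric",
                 rates = "data.frame")
)

setValidity("MMFit", function(object) {
  msg <- character(0)
  if (object@kcat <= 0 || object@km <= 0)
    msg <- c(msg, "kcat and Km must be positive")
  if (abs(object@efficiency - object@kcat / object@km) >
      1e-8 * object@efficiency)
    msg <- c(msg, "efficiency must equal kcat/Km")
  if (length(msg)) msg else TRUE
})

#' Protein structure as an annotated atom table
#'
#' A flat atom table sufficient for surface-area and contact analysis:
#' chain, residue number/name, atom name, element, coordinates (Angstrom)
#' and an assigned van der Waals radius for every atom.
#'
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety,
#'   element, x, y, z, radius.
#' @exportClass ProteinStructure
setClass("ProteinStructure", representation(atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z",
            "radius")
  msg <- character(0)
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("atoms must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(a) < 1) msg <- c(msg, "structure must contain at least one atom")
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      msg <- c(msg, "coordinates must be finite")
    if (anyNA(a$radius) || any(a$radius <= 0))
      msg <- c(msg, "every atom needs a positive van der Waals radius")
  }
  if (length(msg)) msg else TRUE
})

#' Protein-protein interface report
#'
#' Per-residue buried surface areas, polarity classes and inter-chain
#' hydrogen bonds for a two-chain complex, from solvent-accessible surface
#' area (SASA) differencing between the isolated chains and the complex.
#'
#' @slot residues data.frame with one row per interface residue: chain,
#'   resno, resid, sasaMonomer, sasaComplex, buried, relativeBuried,
#'   polarity, hbond.
#' @slot totalBuriedPerMonomer numeric, mean buried area per chain (A^2).
#' @slot totalBuriedPerChain named numeric, buried area per chain (A^2).
#' @slot nResidues integer, rows in \code{residues}.
#' @slot pctApolar numeric, percentage of interface residues classified
#'   apolar.
#' @slot hbonds data.frame of inter-chain donor/acceptor pairs with
#'   distances (A).
#' @exportClass InterfaceReport
setClass("InterfaceReport",
  representation(residues = "data.frame", totalBuriedPerMonomer = "numeric",
                 totalBuriedPerChain = "numeric", nResidues = "integer",
                 pctApolar = "numeric", hbonds = "data.frame")
)

setValidity("InterfaceReport", function(object) {
  msg <- character(0)
  if (object@nResidues != nrow(object@residues))
    msg <- c(msg, "nResidues must equal nrow(residues)")
  if (object@nResidues > 0) {
    rb <- object@residues$relativeBuried
    if (any(rb < -1e-6) || any(rb > 100 + 1e-6))
      msg <- c(msg, "relativeBuried must lie in [0, 100]")
    pa <- 100 * mean(object@residues$polarity == "apolar")
    if (abs(pa - object@pctApolar) > 1e-6)
      msg <- c(msg, "pctApolar inconsistent with residue polarities")
  }
  if (length(msg)) msg else TRUE
})
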
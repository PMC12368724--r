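#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("elutionVolume", "Chromatogram", function(object) object@volume)
#' @rdname accessors
setMethod("signal", "Chromatogram", function(object) object@signal)

#' Metadata of a Chromatogram
#' @param object a \linkS4class{Chromatogram}.
#' @return the metadata list.
#' @export
chromMetadata <- function(object) {
  stopifnot(is(object, "Chromatogram"))
  object@metadata
}

#' @rdname accessors
setMethod("peakArea", "Peak", function(object) object@area)
#' @rdname accessors
setMethod("peakApex", "Peak", function(object) object@apex)

#' @rdname accessors
setMethod("monomerConc", "SpeciesConcentrations", function(object) object@M)
#' @rdname accessors
setMethod("dimerConc", "SpeciesConcentrations", function(object) object@D)
#' @rdname accessors
setMethod("totalConc", "SpeciesConcentrations", function(object) object@cTotal)

setMethod("length", "SpeciesConcentrations", function(x) length(x@M))

#' @export
#' @method as.data.frame SpeciesConcentrations
as.data.frame.SpeciesConcentrations <- function(x, ...) {
  data.frame(M = x@M, D = x@D, cTotal = x@cTotal, flagged = x@flagged)
}

#' @rdname accessors
setMethod("kd", "DimerEquilibriumFit", function(object) object@kd)
#' @rdname accessors
setMethod("ci95", "DimerEquilibriumFit", function(object) object@ci95)

#' @rdname accessors
setMethod("kcat", "MMFit", function(object) object@kcat)
#' @rdname accessors
setMethod("km", "MMFit", function(object) object@km)
#' @rdname accessors
setMethod("efficiency", "MMFit", function(object) object@efficiency)

#' @rdname accessors
setMethod("interfaceHbonds", "InterfaceReport", function(object) object@hbonds)
#' @rdname accessors
setMethod("buriedArea", "InterfaceReport", function(object)
  object@totalBuriedPerMonomer)

#' Interface residue table
#' @param object an \linkS4class{InterfaceReport}.
#' @return data.frame of per-residue interface statistics.
#' @export
interfaceResidueTable <- function(object) {
  stopifnot(is(object, "InterfaceReport"))
  object@residues
}

#' Chain identifiers present in a structure
#' @param object a \linkS4class{ProteinStructure}.
#' @return character vector of chain ids.
#' @export
structureChains <- function(object) {
  stopifnot(is(object, "ProteinStructure"))
  unique(object@atoms$chain)
}

#' Atom table of a structure
#' @param object a \linkS4class{ProteinStructure}.
#' @return data.frame of atoms.
#' @export
atomTable <- function(object) {
  stopifnot(is(object, "ProteinStructure"))
  object@atoms
}

setMethod("show", "Chromatogram", function(object) {
  n <- length(object@volume)
  cat("Chromatogram with", n, "points")
  if (n > 0)
    cat(sprintf(" (%.2f-%.2f mL)", object@volume[1], object@volume[n]))
  ct <- object@metadata$cTotal
  if (!is.null(ct)) cat(sprintf(", c_total = %g uM", ct))
  if (!is.null(object@metadata$buffer))
    cat(",", object@metadata$buffer)
  cat("\n")
})

setMethod("show", "Peak", function(object) {
  cat(sprintf("Peak: window %.2f-%.2f mL, apex %.2f mL, area %.4g AU*mL\n",
              object@lo, object@hi, object@apex, object@area))
})

setMethod("show", "SpeciesConcentrations", function(object) {
  cat("SpeciesConcentrations:", length(object@M), "samples\n")
  print(utils::head(as.data.frame(object), 8))
  if (length(object@M) > 8) cat("...\n")
})

setMethod("show", "DimerEquilibriumFit", function(object) {
  cat(sprintf("Dimer dissociation fit (%s)\n", object@method))
  cat(sprintf("  K_D = %.4g uM", object@kd))
  if (is.finite(object@stderr)) cat(sprintf(" (se %.3g)", object@stderr))
  if (all(is.finite(object@ci95)))
    cat(sprintf(", 95%% CI [%.4g, %.4g]", object@ci95[1], object@ci95[2]))
  cat(sprintf("\n  n = %d points, R^2 = %.4f\n", object@nPoints,
              object@rSquared))
})

setMethod("show", "KineticsDataset", function(object) {
  cat(sprintf(
    "KineticsDataset: %d substrate concentrations x %d times, E0 = %g uM\n",
    length(object@substrate), length(object@times), object@E0))
})

setMethod("show", "MMFit", function(object) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  kcat = %.4g +/- %.2g min^-1\n", object@kcat, object@kcatSd))
  cat(sprintf("  Km   = %.4g +/- %.2g mM\n", object@km, object@kmSd))
  cat(sprintf("  kcat/Km = %.4g +/- %.2g min^-1 mM^-1\n",
              object@efficiency, object@efficiencySd))
})

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat(sprintf("ProteinStructure: %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              nrow(unique(a[, c("chain", "resno")]))))
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport: %d interface residues, %.1f A^2 buried per monomer\n",
              object@nResidues, object@totalBuriedPerMonomer))
  cat(sprintf("  %.0f%% apolar, %d inter-chain hydrogen bonds\n",
              object@pctApolar, nrow(object@hbonds)))
})
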
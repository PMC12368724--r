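#' @include AllClasses.R
NULL

#' Accessors for SECdimer classes
#'
#' Small accessor generics: \code{elutionVolume} and \code{signal} for
#' \linkS4class{Chromatogram}; \code{peakArea} and \code{peakApex} for
#' \linkS4class{Peak}; \code{monomerConc}, \code{dimerConc} and
#' \code{totalConc} for \linkS4class{SpeciesConcentrations}; \code{kd},
#' \code{ci95} for \linkS4class{DimerEquilibriumFit}; \code{kcat},
#' \code{km}, \code{efficiency} for \linkS4class{MMFit};
#' \code{interfaceHbonds}, \code{buriedArea} for
#' \linkS4class{InterfaceReport}.
#'
#' @param object an object of the documented class.
#' @return The slot value (numeric vector or data.frame).
#' @name accessors
#' @aliases elutionVolume signal peakArea peakApex monomerConc dimerConc
#'   totalConc kd ci95 kcat km efficiency interfaceHbonds buriedArea
NULL

#' @rdname accessors
#' @export
setGeneric("elutionVolume", function(object) standardGeneric("elutionVolume"))
#' @rdname accessors
#' @export
setGeneric("signal", function(object) standardGeneric("signal"))
#' @rdname accessors
#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))
#' @rdname accessors
#' @export
setGeneric("peakApex", function(object) standardGeneric("peakApex"))
#' @rdname accessors
#' @export
setGeneric("monomerConc", function(object) standardGeneric("monomerConc"))
#' @rdname accessors
#' @export
setGeneric("dimerConc", function(object) standardGeneric("dimerConc"))
#' @rdname accessors
#' @export
setGeneric("totalConc", function(object) standardGeneric("totalConc"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("ci95", function(object) standardGeneric("ci95"))
#' @rdname accessors
#' @export
setGeneric("kcat", function(object) standardGeneric("kcat"))
#' @rdname accessors
#' @export
setGeneric("km", function(object) standardGeneric("km"))
#' @rdname accessors
#' @export
setGeneric("efficiency", function(object) standardGeneric("efficiency"))
#' @rdname accessors
#' @export
setGeneric("interfaceHbonds", function(object)
  standardGeneric("interfaceHbonds"))
#' @rdname accessors
#' @export
setGeneric("buriedArea", function(object) standardGeneric("buriedArea"))
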
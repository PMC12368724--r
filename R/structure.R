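#' @include AllClasses.R
NULL

#' Element-based van der Waals radii (Angstrom)
#'
#' The radius set used for surface-area calculations: C 1.70, N 1.55,
#' O 1.52, S 1.80, P 1.80, H 1.20.
#'
#' @return named numeric vector of radii.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB file into a ProteinStructure
#'
#' Parses ATOM records (via \code{bio3d::read.pdb}); HETATM records and
#' waters are excluded by default, alternate locations other than blank or
#' \code{'A'} are dropped, and every atom is assigned an element-based van
#' der Waals radius. Atoms whose element is not in the radius table raise
#' an error unless \code{defaultRadius} is supplied.
#'
#' @param path PDB-format file.
#' @param keepHetatm logical, keep non-water HETATM records.
#' @param radii named radius table, see \code{\link{defaultVdwRadii}}.
#' @param defaultRadius fallback radius (A) for unknown elements; NULL
#'   (default) makes unknown elements an error.
#' @return a \linkS4class{ProteinStructure}.
#' @export
readPDBStructure <- function(path, keepHetatm = FALSE,
                             radii = defaultVdwRadii(),
                             defaultRadius = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type == "ATOM" | (keepHetatm & a$type == "HETATM")
  keep <- keep & !(a$resid %in% .WATER_RESIDUES)
  keep <- keep & (is.na(a$alt) | a$alt %in% c("", "A"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms parsed from ", path)
  element <- toupper(a$elesy)
  noEl <- is.na(element) | element == ""
  # fall back on the first letter of the atom name
  element[noEl] <- substr(gsub("[^A-Za-z].*", "",
                               gsub("^[0-9]+", "", a$elety[noEl])), 1, 1)
  r <- unname(radii[element])
  if (anyNA(r)) {
    if (is.null(defaultRadius))
      stop("unknown element(s): ",
           paste(unique(element[is.na(r)]), collapse = ", "),
           " (supply defaultRadius to override)")
    r[is.na(r)] <- defaultRadius
  }
  chain <- a$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    chain = chain, resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid, elety = a$elety, element = element,
    x = a$x, y = a$y, z = a$z, radius = r,
    stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = atoms)
}

#' Construct a ProteinStructure from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resid, elety,
#'   element, x, y, z and optionally insert and radius; radii are filled
#'   from \code{radii} by element when absent.
#' @param radii named radius table.
#' @return a \linkS4class{ProteinStructure}.
#' @export
proteinStructure <- function(atoms, radii = defaultVdwRadii()) {
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$radius)) atoms$radius <- unname(radii[atoms$element])
  if (anyNA(atoms$radius))
    stop("unknown element(s): ",
         paste(unique(atoms$element[is.na(atoms$radius)]), collapse = ", "))
  new("ProteinStructure", atoms = atoms)
}

#' Subset a structure by chain
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param chains character vector of chain ids to keep.
#' @return a \linkS4class{ProteinStructure}.
#' @export
selectChains <- function(structure, chains) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- structure@atoms[structure@atoms$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0) stop("chain(s) not found: ",
                         paste(chains, collapse = ","))
  new("ProteinStructure", atoms = a)
}
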
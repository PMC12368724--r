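#' Published reference tables for the Sfbgly homodimer
#'
#' Small published data tables for the GH1 beta-glucosidase of
#' \emph{Spodoptera frugiperda} (Sfbgly, PDB 5CG0), the homodimer whose
#' dissociation this package was written to analyse. They are constructed
#' in code (no external files) and serve as worked-example inputs and
#' regression anchors.
#'
#' \describe{
#'   \item{\code{sfbglyInterfaceTable()}}{The 30 interface residues of one
#'     monomer with their relative buried surface area (\%) and
#'     hydrogen-bond involvement.}
#'   \item{\code{sfbglyMutantTable()}}{Dissociation constants (mM, P100
#'     buffer, 5 C) for the wild type and six single-residue interface
#'     mutants, with the published ddG values (kJ/mol) and hydrogen-bond
#'     site flags. The Y303A variant was observed only as a monomer, so
#'     its K_D is NA (lower bound: above the largest measured value).}
#'   \item{\code{sfbglyKineticsTable()}}{Michaelis-Menten parameters
#'     (NPbglc substrate, 30 C): kcat (min^-1), Km (mM), efficiency
#'     kcat/Km and efficiency relative to wild type (\%), each with sd.}
#'   \item{\code{sfbglyBufferTable()}}{The five sodium phosphate buffers
#'     (pH 6): total phosphate (M), published ionic strength (M) and the
#'     wild-type K_D (uM) measured in each.}
#' }
#'
#' @return A data.frame; see Details.
#' @name sfbglyTables
NULL

#' @rdname sfbglyTables
#' @export
sfbglyInterfaceTable <- function() {
  resno <- c(108, 110, 111, 112, 148, 150, 151, 152, 153, 156, 157, 158,
             159, 163, 166, 169, 196, 205, 206, 207, 210, 211, 214, 218,
             301, 302, 303, 304, 305, 348)
  resid <- c("THR", "MET", "ALA", "ASN", "LYS", "GLN", "GLU", "LEU", "GLY",
             "ALA", "ASN", "PRO", "LEU", "TRP", "ASP", "ARG", "TYR", "LEU",
             "ASN", "ALA", "MET", "GLY", "LEU", "ASN", "GLN", "GLY", "TYR",
             "PRO", "TRP", "PRO")
  relativeBuried <- c(10, 80, 70, 80, 10, 20, 60, 90, 100, 100, 100, 60,
                      60, 60, 80, 10, 20, 70, 10, 40, 70, 80, 70, 10, 30,
                      40, 80, 30, 40, 10)
  hbond <- resno %in% c(156, 157, 166, 305)
  data.frame(resno = resno, resid = resid,
             relativeBuried = relativeBuried, hbond = hbond,
             stringsAsFactors = FALSE)
}

#' @rdname sfbglyTables
#' @export
sfbglyMutantTable <- function() {
  data.frame(
    name = c("wild-type", "N112S", "N157S", "D166S", "M210A", "L214A",
             "Y303A"),
    kd = c(0.008, 1.2, 0.028, 0.1, 3.6, 5.4, NA),   # mM, P100, 5 C
    ddgPublished = c(NA, 12, 2.9, 6.6, 14, 15, NA),  # kJ/mol
    hbondSite = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' @rdname sfbglyTables
#' @export
sfbglyKineticsTable <- function() {
  data.frame(
    name = c("wild-type", "N112S", "N157S", "D166S", "M210A", "L214A",
             "Y303A"),
    kcat = c(143, 140, 66, 80, 116, 167, 73),
    kcatSd = c(2, 4, 2, 1, 2, 7, 3),
    km = c(1.1, 1.2, 1.1, 2.2, 1.1, 1.9, 2.6),
    kmSd = c(0.1, 0.2, 0.2, 0.2, 0.2, 0.4, 0.5),
    efficiency = c(130, 117, 60, 35, 105, 84, 27),
    efficiencySd = c(14, 23, 13, 4, 21, 21, 7),
    relativeEfficiency = c(100, 90, 46, 28, 81, 65, 22),
    relativeEfficiencySd = c(NA, 27, 14, 7, 24, 23, 7),
    stringsAsFactors = FALSE)
}

#' @rdname sfbglyTables
#' @export
sfbglyBufferTable <- function() {
  data.frame(
    buffer = c("P100", "P75", "P50", "P25", "P5"),
    phosphateM = c(0.100, 0.075, 0.050, 0.025, 0.005),
    ionicStrengthPublished = c(0.218, 0.163, 0.109, 0.054, 0.011),
    kdUm = c(7, 9.9, 9.5, 78, 135),
    stringsAsFactors = FALSE)
}
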
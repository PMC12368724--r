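.GAS_CONSTANT <- 8.314  # J/(mol K)

#' Dissociation free-energy change between two variants
#'
#' \deqn{\Delta\Delta G^0_{diss} = RT \ln(K_{D,variant}/K_{D,reference})}
#' Positive values mean the variant dimer dissociates more easily
#' (destabilized) than the reference. Both K_D values must be in the same
#' (arbitrary) concentration units; only their ratio enters.
#'
#' @param kdVariant,kdReference dissociation constants (same units), > 0.
#' @param temperature absolute temperature (K); default 278.15 K (5 C, the
#'   temperature of the cold-room SEC experiments this analysis targets).
#' @return free-energy change in kJ/mol (vectorized over
#'   \code{kdVariant}).
#' @examples
#' ddgDissociation(0.028, 0.008)  # ~2.9 kJ/mol
#' @export
ddgDissociation <- function(kdVariant, kdReference, temperature = 278.15) {
  if (any(kdVariant <= 0) || any(kdReference <= 0))
    stop("dissociation constants must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  .GAS_CONSTANT * temperature * log(kdVariant / kdReference) / 1000
}

#' Standard dissociation free energy from K_D
#'
#' \deqn{\Delta G^0_{diss} = -RT \ln K_D} with \eqn{K_D} in molar units
#' (1 M standard state). Positive for \eqn{K_D < 1} M: free energy is
#' required to dissociate a stable dimer.
#'
#' @param kd dissociation constant in M, > 0.
#' @param temperature absolute temperature (K).
#' @return kJ/mol.
#' @export
dgDissociation <- function(kd, temperature = 278.15) {
  if (any(kd <= 0)) stop("kd must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  -.GAS_CONSTANT * temperature * log(kd) / 1000
}

#' Hydrogen-bond energy budget
#'
#' Sums per-bond free-energy contributions weighted by their multiplicity
#' (e.g. bonds duplicated by the two-fold symmetry of an isologous
#' interface).
#'
#' @param ddg numeric, per-bond contributions (kJ/mol).
#' @param multiplicity integer counts (>= 1), recycled against \code{ddg}.
#' @return total energy (kJ/mol); 0 for empty input.
#' @examples
#' hbondEnergyBudget(c(2.9, 6.6), c(2, 2))  # 19 kJ/mol
#' @export
hbondEnergyBudget <- function(ddg, multiplicity = 1) {
  if (length(ddg) == 0) return(0)
  multiplicity <- rep_len(multiplicity, length(ddg))
  if (any(multiplicity < 1)) stop("multiplicities must be >= 1")
  sum(ddg * multiplicity)
}

#' Hydrophobic burial energy
#'
#' Free-energy gain of burying apolar surface, modelled as a constant
#' coefficient per buried square Angstrom (default 54.4 J/mol/A^2, an
#' empirical transfer value for protein interfaces).
#'
#' @param buriedApolarArea buried apolar area (A^2), >= 0.
#' @param gamma surface coefficient (J/mol/A^2).
#' @return energy (kJ/mol).
#' @export
hydrophobicEnergy <- function(buriedApolarArea, gamma = 54.4) {
  if (any(buriedApolarArea < 0)) stop("area must be non-negative")
  gamma * buriedApolarArea / 1000
}

#' Ionic strength of a sodium phosphate buffer
#'
#' Henderson-Hasselbalch speciation of the H2PO4- / HPO4^2- couple at the
#' given pH and second pKa, sodium counterion fixed by electroneutrality,
#' then \eqn{I = \frac{1}{2}\sum c_i z_i^2}. pKa1 and pKa3 are ignored:
#' near neutral pH, H3PO4 and PO4^3- are negligible.
#'
#' @param phosphateTotal total phosphate (M), >= 0.
#' @param pH buffer pH (0 < pH < 14).
#' @param pKa2 second dissociation constant of phosphoric acid; default
#'   7.20.
#' @return ionic strength (M).
#' @examples
#' phosphateIonicStrength(0.1, pH = 7.2)  # 0.200 M
#' phosphateIonicStrength(0.1, pH = 6.0)  # ~0.112 M
#' @export
phosphateIonicStrength <- function(phosphateTotal, pH, pKa2 = 7.20) {
  if (any(phosphateTotal < 0)) stop("phosphateTotal must be non-negative")
  if (any(pH <= 0) || any(pH >= 14)) stop("pH must be in (0, 14)")
  ratio <- 10^(pH - pKa2)                 # [HPO4^2-]/[H2PO4-]
  h2po4 <- phosphateTotal / (1 + ratio)
  hpo4 <- phosphateTotal - h2po4
  na <- h2po4 + 2 * hpo4                  # electroneutrality
  0.5 * (na * 1 + h2po4 * 1 + hpo4 * 4)
}

#' Mutant free-energy table
#'
#' Computes \code{\link{ddgDissociation}} for a table of variant K_D
#' values against a named reference row. Rows with non-determinable K_D
#' (NA, e.g. a variant observed only as a monomer) receive a lower bound:
#' the largest \eqn{\Delta\Delta G} among determinable variants, reported
#' in the \code{note} column as a \code{">"} bound.
#'
#' @param kdTable data.frame with columns \code{name} and \code{kd}
#'   (any consistent concentration unit).
#' @param reference name of the reference row (e.g. \code{"wild-type"}).
#' @param temperature absolute temperature (K).
#' @return the input with columns \code{ddg} (kJ/mol) and \code{note}
#'   appended.
#' @export
ddgTable <- function(kdTable, reference = "wild-type",
                     temperature = 278.15) {
  stopifnot(all(c("name", "kd") %in% names(kdTable)))
  ref <- kdTable$kd[kdTable$name == reference]
  if (length(ref) != 1 || is.na(ref)) stop("reference row not found or NA")
  out <- kdTable
  out$ddg <- NA_real_
  ok <- !is.na(out$kd)
  out$ddg[ok] <- ddgDissociation(out$kd[ok], ref, temperature)
  out$note <- ""
  nd <- is.na(out$kd)
  if (any(nd)) {
    bound <- max(out$ddg, na.rm = TRUE)
    out$note[nd] <- sprintf("not determinable; ddG > %.3g kJ/mol", bound)
  }
  out
}
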
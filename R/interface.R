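#' @include sasa.R
NULL

.APOLAR_RESIDUES <- c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "MET",
                      "PHE", "TRP", "TYR")
.POLAR_RESIDUES <- c("SER", "THR", "CYS", "ASN", "GLN", "ASP", "GLU",
                     "LYS", "ARG", "HIS")

#' Classify residue polarity
#'
#' Binary polarity scheme for interface bookkeeping: GLY, ALA, VAL, LEU,
#' ILE, PRO, MET, PHE, TRP and TYR are apolar (aromatic hydroxyl
#' notwithstanding, TYR sides with the apolar class here); the remaining
#' standard residues are polar.
#'
#' @param residueName character vector of standard 3-letter residue names.
#' @return character vector, \code{"apolar"} or \code{"polar"}.
#' @export
classifyPolarity <- function(residueName) {
  rn <- toupper(residueName)
  unknown <- !(rn %in% c(.APOLAR_RESIDUES, .POLAR_RESIDUES))
  if (any(unknown))
    stop("unknown residue name(s): ", paste(unique(rn[unknown]), collapse = ", "))
  ifelse(rn %in% .APOLAR_RESIDUES, "apolar", "polar")
}

# Hydrogen-bond-capable heavy atoms by residue template. Crystal structures
# lack hydrogens, so donor capability is inferred from the parent heavy
# atom; the criterion is distance-only (no angle term).
.hbDonorAtoms <- function(resid, elety) {
  bb <- elety == "N" & resid != "PRO"
  sc <- (resid == "ARG" & elety %in% c("NE", "NH1", "NH2")) |
    (resid == "LYS" & elety == "NZ") |
    (resid == "ASN" & elety == "ND2") |
    (resid == "GLN" & elety == "NE2") |
    (resid == "HIS" & elety %in% c("ND1", "NE2")) |
    (resid == "TRP" & elety == "NE1") |
    (resid == "SER" & elety == "OG") |
    (resid == "THR" & elety == "OG1") |
    (resid == "TYR" & elety == "OH")
  bb | sc
}

.hbAcceptorAtoms <- function(resid, elety) {
  bb <- elety %in% c("O", "OXT")
  sc <- (resid == "ASP" & elety %in% c("OD1", "OD2")) |
    (resid == "GLU" & elety %in% c("OE1", "OE2")) |
    (resid == "ASN" & elety == "OD1") |
    (resid == "GLN" & elety == "OE1") |
    (resid == "HIS" & elety %in% c("ND1", "NE2")) |
    (resid == "SER" & elety == "OG") |
    (resid == "THR" & elety == "OG1") |
    (resid == "TYR" & elety == "OH")
  bb | sc
}

#' Detect inter-chain hydrogen bonds
#'
#' Distance-only criterion on heavy atoms: donor-capable N/O of one chain
#' within \code{maxDa} (default 3.5 A) of an acceptor-capable N/O of the
#' other. Both directions are scanned, so symmetry-related bonds of an
#' isologous interface are each reported.
#'
#' @param structure a \linkS4class{ProteinStructure} containing both
#'   chains.
#' @param chainA,chainB chain identifiers.
#' @param maxDa donor-acceptor heavy-atom distance cutoff (A).
#' @return data.frame with donor chain/residue/atom, acceptor
#'   chain/residue/atom and distance (A); zero rows when no bond is found.
#' @export
detectHbonds <- function(structure, chainA = "A", chainB = "B",
                         maxDa = 3.5) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- structure@atoms
  for (ch in c(chainA, chainB))
    if (!ch %in% a$chain) stop("chain not present: ", ch)
  empty <- data.frame(donorChain = character(0), donorResno = integer(0),
                      donorResid = character(0), donorAtom = character(0),
                      acceptorChain = character(0),
                      acceptorResno = integer(0),
                      acceptorResid = character(0),
                      acceptorAtom = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  .pairs <- function(don, acc) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(empty)
    d <- sqrt(outer(don$x, acc$x, "-")^2 + outer(don$y, acc$y, "-")^2 +
                outer(don$z, acc$z, "-")^2)
    hit <- which(d <= maxDa, arr.ind = TRUE)
    if (nrow(hit) == 0) return(empty)
    data.frame(donorChain = don$chain[hit[, 1]],
               donorResno = don$resno[hit[, 1]],
               donorResid = don$resid[hit[, 1]],
               donorAtom = don$elety[hit[, 1]],
               acceptorChain = acc$chain[hit[, 2]],
               acceptorResno = acc$resno[hit[, 2]],
               acceptorResid = acc$resid[hit[, 2]],
               acceptorAtom = acc$elety[hit[, 2]],
               distance = d[hit], stringsAsFactors = FALSE)
  }
  isDon <- .hbDonorAtoms(a$resid, a$elety) & a$element %in% c("N", "O")
  isAcc <- .hbAcceptorAtoms(a$resid, a$elety) & a$element %in% c("N", "O")
  res <- rbind(
    .pairs(a[isDon & a$chain == chainA, ], a[isAcc & a$chain == chainB, ]),
    .pairs(a[isDon & a$chain == chainB, ], a[isAcc & a$chain == chainA, ]))
  res[order(res$donorChain, res$donorResno, res$distance), , drop = FALSE]
}

#' Characterize a two-chain protein interface
#'
#' Computes SASA for each isolated chain and for the complex, then reports
#' every residue whose buried area (isolated minus complex SASA) exceeds
#' \code{minBuried}. Relative buried area is
#' \code{100 * buried / sasaMonomer} -- the share of the residue's
#' solvent-accessible surface in the free monomer that the partner chain
#' occludes. Polarity uses \code{\link{classifyPolarity}} and inter-chain
#' hydrogen bonds come from \code{\link{detectHbonds}}.
#'
#' @param structure a \linkS4class{ProteinStructure} with both chains.
#' @param chainA,chainB chain identifiers.
#' @param minBuried minimum buried area (A^2) for a residue to be listed.
#' @param probe probe radius (A).
#' @param nPoints sphere sample points per atom.
#' @param maxDa hydrogen-bond distance cutoff (A).
#' @return an \linkS4class{InterfaceReport}.
#' @export
interfaceResidues <- function(structure, chainA = "A", chainB = "B",
                              minBuried = 0.1, probe = 1.4, nPoints = 960,
                              maxDa = 3.5) {
  stopifnot(is(structure, "ProteinStructure"))
  complexAB <- selectChains(structure, c(chainA, chainB))
  sasaCx <- shrakeRupleySasa(complexAB, probe, nPoints)$residue
  perChain <- lapply(c(chainA, chainB), function(ch) {
    iso <- shrakeRupleySasa(selectChains(structure, ch), probe,
                            nPoints)$residue
    cx <- sasaCx[sasaCx$chain == ch, ]
    key <- paste(iso$resno, iso$insert)
    cxKey <- paste(cx$resno, cx$insert)
    iso$sasaComplex <- cx$sasa[match(key, cxKey)]
    iso$buried <- pmax(0, iso$sasa - iso$sasaComplex)
    iso
  })
  all <- do.call(rbind, perChain)
  totals <- vapply(perChain, function(d) sum(d$buried), numeric(1))
  names(totals) <- c(chainA, chainB)
  sel <- all[all$buried > minBuried, , drop = FALSE]
  hb <- detectHbonds(structure, chainA, chainB, maxDa)
  if (nrow(sel)) {
    residues <- data.frame(
      chain = sel$chain, resno = sel$resno, resid = sel$resid,
      sasaMonomer = sel$sasa, sasaComplex = sel$sasaComplex,
      buried = sel$buried,
      relativeBuried = pmin(100, 100 * sel$buried / pmax(sel$sasa, 1e-12)),
      polarity = classifyPolarity(sel$resid),
      hbond = paste(sel$chain, sel$resno) %in%
        c(paste(hb$donorChain, hb$donorResno),
          paste(hb$acceptorChain, hb$acceptorResno)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    residues <- data.frame(chain = character(0), resno = integer(0),
                           resid = character(0), sasaMonomer = numeric(0),
                           sasaComplex = numeric(0), buried = numeric(0),
                           relativeBuried = numeric(0),
                           polarity = character(0), hbond = logical(0),
                           stringsAsFactors = FALSE)
  }
  new("InterfaceReport", residues = residues,
      totalBuriedPerMonomer = mean(totals), totalBuriedPerChain = totals,
      nResidues = nrow(residues),
      pctApolar = if (nrow(residues)) 100 * mean(residues$polarity == "apolar")
                  else NA_real_,
      hbonds = hb)
}
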
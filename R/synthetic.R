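#' @include AllClasses.R
NULL

#' Monomer and dimer concentrations at equilibrium
#'
#' Solves the monomer-dimer equilibrium M + M <-> D with dissociation
#' constant \eqn{K_D = [M]^2/[D]} under the mass balance
#' \eqn{c_{total} = [M] + 2[D]} (monomer-equivalent total). The quadratic
#' has the closed-form positive root
#' \deqn{[M] = \frac{-K_D + \sqrt{K_D^2 + 8 K_D c}}{4} = \frac{2c}{1 + \sqrt{1 + 8c/K_D}},}
#' the second form being numerically stable for large \eqn{K_D}.
#'
#' @param cTotal numeric vector, total protein concentration (uM,
#'   monomer-equivalent); all > 0.
#' @param kd numeric scalar, dissociation constant (uM); > 0.
#' @return A \linkS4class{SpeciesConcentrations} with one entry per
#'   element of \code{cTotal}.
#' @examples
#' sp <- simulateEquilibriumSpecies(cTotal = 7, kd = 7)
#' monomerConc(sp)  # 3.5
#' dimerConc(sp)    # 1.75
#' @export
simulateEquilibriumSpecies <- function(cTotal, kd) {
  if (!is.numeric(cTotal) || any(cTotal <= 0))
    stop("cTotal must be positive")
  if (!is.numeric(kd) || length(kd) != 1L || kd <= 0)
    stop("kd must be a positive scalar")
  M <- 2 * cTotal / (1 + sqrt(1 + 8 * cTotal / kd))
  D <- (cTotal - M) / 2
  speciesConcentrations(M = M, D = D, cTotal = cTotal)
}

#' Construct a SpeciesConcentrations object
#'
#' @param M,D numeric vectors of monomer (uM) and dimer (uM, dimer-molar)
#'   concentrations.
#' @param cTotal total concentration (uM, monomer-equivalent); defaults to
#'   \code{M + 2*D}.
#' @return a validated \linkS4class{SpeciesConcentrations}.
#' @export
speciesConcentrations <- function(M, D, cTotal = M + 2 * D) {
  fD <- ifelse(cTotal > 0, 2 * D / cTotal, 0)
  new("SpeciesConcentrations", M = as.numeric(M), D = as.numeric(D),
      cTotal = as.numeric(cTotal),
      flagged = fD < 0.01 | fD > 0.99)
}

#' Simulate a SEC dilution series
#'
#' Generates one synthetic chromatogram per total concentration. Each trace
#' carries two Gaussian elution peaks -- dimer (default center 25 mL) and
#' monomer (default center 35 mL) -- whose noise-free areas are
#' proportional to the species mass fractions \eqn{[M]/c} and \eqn{2[D]/c}
#' at the loading equilibrium for the chosen true \eqn{K_D}. The detector
#' response is assumed proportional to protein mass and identical per unit
#' mass for both species (A280-like), so the area ratio equals the mass
#' ratio. Peak areas are perturbed by mean-one lognormal noise with
#' coefficient of variation \code{noiseCv}, and a linear baseline
#' \code{baselineSlope * volume} is added. Interconversion during elution
#' is not modelled: peaks represent populations frozen at the loading
#' equilibrium, mimicking SEC run cold to slow monomer-dimer exchange.
#'
#' @param trueKd numeric, generating dissociation constant (uM).
#' @param cTotals numeric vector, loaded total concentrations (uM).
#' @param monomerCenter,dimerCenter peak centers (mL);
#'   \code{monomerCenter > dimerCenter} (the larger species elutes first).
#' @param monomerWidth,dimerWidth Gaussian sigma (mL).
#' @param noiseCv fractional multiplicative noise on peak areas (>= 0).
#' @param baselineSlope linear baseline slope (AU/mL).
#' @param responseFactor detector response (AU*mL per uM of loaded
#'   protein); scales all areas.
#' @param volumeGrid elution-volume grid (mL).
#' @param buffer buffer label stored in the metadata.
#' @param seed optional integer; when given, \code{set.seed(seed)} is
#'   called so the series is reproducible.
#' @return list of \linkS4class{Chromatogram}, one per \code{cTotals}
#'   entry. Each metadata list records \code{cTotal}, \code{buffer},
#'   \code{temperature}, the realized (noisy) areas \code{areaM},
#'   \code{areaD} and the noise-free areas \code{trueAreaM},
#'   \code{trueAreaD}.
#' @export
simulateDilutionSeries <- function(trueKd, cTotals,
                                   monomerCenter = 35, dimerCenter = 25,
                                   monomerWidth = 0.8, dimerWidth = 0.8,
                                   noiseCv = 0, baselineSlope = 0,
                                   responseFactor = 1,
                                   volumeGrid = seq(15, 45, by = 0.02),
                                   buffer = "P100", seed = NULL) {
  if (trueKd <= 0) stop("trueKd must be positive")
  if (any(cTotals <= 0)) stop("all cTotals must be positive")
  if (monomerCenter <= dimerCenter)
    stop("monomerCenter must exceed dimerCenter (larger species elutes earlier)")
  if (noiseCv < 0) stop("noiseCv must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + noiseCv^2))
  sp <- simulateEquilibriumSpecies(cTotals, trueKd)
  lapply(seq_along(cTotals), function(i) {
    ct <- cTotals[i]
    # mass fractions map to areas through a common response factor
    trueAreaM <- responseFactor * sp@M[i]
    trueAreaD <- responseFactor * 2 * sp@D[i]
    fac <- if (noiseCv > 0)
      exp(stats::rnorm(2, mean = -sdlog^2 / 2, sd = sdlog)) else c(1, 1)
    areaM <- trueAreaM * fac[1]
    areaD <- trueAreaD * fac[2]
    sig <- areaM * stats::dnorm(volumeGrid, monomerCenter, monomerWidth) +
      areaD * stats::dnorm(volumeGrid, dimerCenter, dimerWidth) +
      baselineSlope * volumeGrid
    new("Chromatogram", volume = volumeGrid, signal = sig,
        metadata = list(cTotal = ct, buffer = buffer, temperature = 5,
                        sampleId = sprintf("sim_%02d", i),
                        areaM = areaM, areaD = areaD,
                        trueAreaM = trueAreaM, trueAreaD = trueAreaD,
                        trueKd = trueKd))
  })
}

#' Simulate Michaelis-Menten product time courses
#'
#' Product accumulation is linear in time at the initial rate
#' \eqn{v_0 = k_{cat} E_0 V [S]/(K_m + [S])} (nmol/min for \code{kcat} in
#' min^-1, \code{E0} in uM and \code{reactionVolume} in uL), with additive
#' Gaussian noise. Noise can be specified as a constant standard deviation
#' in nmol (\code{noiseSd}) and/or a fraction of the true product at each
#' point (\code{noiseCv}); the two contributions add in quadrature.
#' Negative noisy readings are truncated at zero.
#'
#' @param kcat turnover number (min^-1).
#' @param km Michaelis constant (mM).
#' @param E0 enzyme concentration in the assay (uM).
#' @param substrateConcs substrate concentrations (mM).
#' @param times sampling times (min), strictly increasing.
#' @param noiseSd additive noise sd (nmol).
#' @param noiseCv fractional noise (sd = noiseCv * true product).
#' @param reactionVolume assay volume (uL).
#' @param seed optional integer for reproducibility.
#' @return a \linkS4class{KineticsDataset}.
#' @export
simulateTimecourse <- function(kcat, km, E0, substrateConcs,
                               times = c(5, 10, 15, 20),
                               noiseSd = 0, noiseCv = 0,
                               reactionVolume = 100, seed = NULL) {
  if (kcat <= 0 || km <= 0 || E0 <= 0)
    stop("kcat, km and E0 must be positive")
  if (any(substrateConcs <= 0)) stop("substrate concentrations must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (noiseSd < 0 || noiseCv < 0) stop("noise parameters must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  enzymeNmol <- E0 * reactionVolume * 1e-3   # uM * uL = pmol; /1000 -> nmol
  v0 <- kcat * enzymeNmol * substrateConcs / (km + substrateConcs)
  truth <- outer(v0, times)
  sd <- sqrt(noiseSd^2 + (noiseCv * truth)^2)
  prod <- truth
  if (any(sd > 0))
    prod <- truth + stats::rnorm(length(truth), 0, as.vector(sd))
  prod <- pmax(prod, 0)
  dim(prod) <- dim(truth)
  dimnames(prod) <- list(S = signif(substrateConcs, 4), t = times)
  new("KineticsDataset", substrate = substrateConcs, times = times,
      product = prod, E0 = E0, reactionVolume = reactionVolume)
}
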
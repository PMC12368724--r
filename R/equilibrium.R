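#' @include AllClasses.R synthetic.R
NULL

#' Convert peak areas to species concentrations
#'
#' With a mass-proportional detector, the monomer mass fraction is
#' \code{areaM / (areaM + areaD)}. Combined with the total loaded
#' concentration c (uM, monomer-equivalent) this gives
#' \code{[M] = fM * c} and \code{[D] = (1 - fM) * c / 2} ([D] in
#' dimer-molar units), so the mass balance \code{[M] + 2[D] = c} holds by
#' construction. Samples with dimer mass fraction below 1\% or above 99\%
#' are flagged (high leverage in the linearized fit) but never dropped.
#'
#' @param areaM,areaD monomer and dimer peak areas (AU*mL), vectorized;
#'   non-negative and not both zero.
#' @param cTotal total protein concentration (uM, monomer-equivalent).
#' @return a \linkS4class{SpeciesConcentrations}.
#' @export
speciesFromAreas <- function(areaM, areaD, cTotal) {
  n <- max(length(areaM), length(areaD), length(cTotal))
  areaM <- rep_len(areaM, n); areaD <- rep_len(areaD, n)
  cTotal <- rep_len(cTotal, n)
  if (any(areaM < 0) || any(areaD < 0)) stop("areas must be non-negative")
  if (any(areaM + areaD == 0)) stop("both peak areas are zero")
  if (any(cTotal <= 0)) stop("cTotal must be positive")
  fM <- areaM / (areaM + areaD)
  sp <- speciesConcentrations(M = fM * cTotal,
                              D = (1 - fM) * cTotal / 2,
                              cTotal = cTotal)
  if (any(sp@flagged))
    warning(sum(sp@flagged),
            " sample(s) with dimer fraction <1% or >99% (high leverage)")
  sp
}

#' Estimate K_D from the linearized equilibrium
#'
#' The dissociation equilibrium \eqn{K_D = [M]^2/[D]} linearizes to
#' \eqn{[M]^2 = K_D [D]}: across a dilution series the points
#' \eqn{([D], [M]^2)} fall on a line through the origin whose slope is
#' \eqn{K_D}. The default is the through-origin least-squares slope
#' \eqn{\sum D M^2 / \sum D^2}; a free-intercept fit is available as a
#' lack-of-fit diagnostic (the model itself has no intercept).
#'
#' @param species a \linkS4class{SpeciesConcentrations} dilution series.
#' @param throughOrigin logical; fit \code{M^2 ~ 0 + D} (default) or
#'   \code{M^2 ~ D}.
#' @return a \linkS4class{DimerEquilibriumFit} with \code{method}
#'   \code{"linear-origin"} or \code{"linear-free-intercept"}.
#' @export
fitKdLinear <- function(species, throughOrigin = TRUE) {
  stopifnot(is(species, "SpeciesConcentrations"))
  n <- length(species)
  minN <- if (throughOrigin) 1L else 2L
  if (n < minN) stop("need at least ", minN, " point(s)")
  x <- species@D; y <- species@M^2
  if (all(x == 0)) stop("degenerate design: all dimer concentrations are zero")
  fit <- if (throughOrigin) stats::lm(y ~ 0 + x) else stats::lm(y ~ x)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  slope <- co["x", "Estimate"]
  se <- if (n > minN) co["x", "Std. Error"] else NA_real_
  if (slope <= 0) stop("non-positive slope: data inconsistent with M+M <-> D")
  yhat <- stats::fitted(fit)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (n > 1 && ssTot > 0) 1 - sum((y - yhat)^2) / ssTot else NA_real_
  new("DimerEquilibriumFit", kd = slope, stderr = se, nPoints = as.integer(n),
      rSquared = r2,
      method = if (throughOrigin) "linear-origin" else "linear-free-intercept",
      ci95 = c(NA_real_, NA_real_), data = species)
}

#' Estimate K_D by direct nonlinear fit of the dimer fraction
#'
#' Diagnostic alternative to the linearization (same model): least-squares
#' fit of the observed dimer mass fraction \eqn{2[D]/c} against the
#' closed-form prediction from the equilibrium at each total
#' concentration. The fit is performed in \eqn{\log_{10} K_D} (the
#' parameter is positive and spans decades), started from the linear
#' estimate. Agrees exactly with the linear estimator on noise-free data.
#'
#' @param species a \linkS4class{SpeciesConcentrations} with at least 2
#'   distinct total concentrations.
#' @return a \linkS4class{DimerEquilibriumFit} with \code{method}
#'   \code{"nonlinear"}.
#' @export
fitKdNonlinear <- function(species) {
  stopifnot(is(species, "SpeciesConcentrations"))
  if (length(unique(species@cTotal)) < 2)
    stop("need at least 2 samples with distinct total concentrations")
  ct <- species@cTotal
  fObs <- 2 * species@D / ct
  predF <- function(lkd) {
    sp <- simulateEquilibriumSpecies(ct, 10^lkd)
    2 * sp@D / ct
  }
  start <- log10(kd(fitKdLinear(species)))
  fit <- minpack.lm::nlsLM(
    fObs ~ predF(lkd), start = list(lkd = start),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv)
    stop("nonlinear K_D fit did not converge: ",
         fit$convInfo$stopMessage)
  lkd <- stats::coef(fit)[["lkd"]]
  kdHat <- 10^lkd
  seL <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["lkd", "Std. Error"]),
    error = function(e) NA_real_)
  se <- kdHat * log(10) * seL        # delta method back to the uM scale
  res <- fObs - predF(lkd)
  ssTot <- sum((fObs - mean(fObs))^2)
  r2 <- if (ssTot > 0) 1 - sum(res^2) / ssTot else NA_real_
  new("DimerEquilibriumFit", kd = kdHat, stderr = se,
      nPoints = as.integer(length(species)), rSquared = r2,
      method = "nonlinear", ci95 = c(NA_real_, NA_real_), data = species)
}

#' Bootstrap confidence interval for K_D
#'
#' Case-resampling bootstrap of the dilution-series points with percentile
#' 95\% interval -- no distributional assumption on the area noise. The
#' point estimate is the fit on the full data; \code{stderr} is the sd of
#' the bootstrap replicates.
#'
#' @param species a \linkS4class{SpeciesConcentrations} with >= 3 points.
#' @param nBoot number of bootstrap resamples (>= 100).
#' @param seed optional integer for reproducibility.
#' @param throughOrigin passed to \code{\link{fitKdLinear}}.
#' @return a \linkS4class{DimerEquilibriumFit} with \code{ci95} and
#'   \code{stderr} filled from the bootstrap.
#' @export
bootstrapKd <- function(species, nBoot = 1000, seed = NULL,
                        throughOrigin = TRUE) {
  stopifnot(is(species, "SpeciesConcentrations"))
  n <- length(species)
  if (n < 3) stop("need at least 3 points to bootstrap")
  if (nBoot < 100) stop("nBoot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  x <- species@D; y <- species@M^2
  boots <- vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (throughOrigin) {
      sum(x[idx] * y[idx]) / sum(x[idx]^2)
    } else {
      stats::coef(stats::lm(y[idx] ~ x[idx]))[2]
    }
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  fit <- fitKdLinear(species, throughOrigin = throughOrigin)
  new("DimerEquilibriumFit", kd = fit@kd, stderr = stats::sd(boots),
      nPoints = fit@nPoints, rSquared = fit@rSquared, method = fit@method,
      ci95 = ci, data = species)
}

#' Full pipeline: chromatograms to a K_D estimate
#'
#' Convenience wrapper running baseline correction, peak integration and
#' area-to-concentration conversion on a list of chromatograms (each with
#' \code{metadata$cTotal} set), then fitting K_D.
#'
#' @param chroms list of \linkS4class{Chromatogram}.
#' @param monomerWindow,dimerWindow integration windows (mL), see
#'   \code{\link{quantifySpeciesPeaks}}.
#' @param method \code{"linear"} (through-origin linearization) or
#'   \code{"nonlinear"}.
#' @param baseline logical, subtract a linear baseline first.
#' @return a \linkS4class{DimerEquilibriumFit}.
#' @export
estimateKdFromChromatograms <- function(chroms,
                                        monomerWindow = c(31, 39),
                                        dimerWindow = c(22, 29),
                                        method = c("linear", "nonlinear"),
                                        baseline = TRUE) {
  method <- match.arg(method)
  sp <- speciesFromChromatograms(chroms, monomerWindow, dimerWindow,
                                 baseline = baseline)
  if (method == "linear") fitKdLinear(sp) else fitKdNonlinear(sp)
}

#' Quantify a chromatogram series into species concentrations
#'
#' @inheritParams estimateKdFromChromatograms
#' @return a \linkS4class{SpeciesConcentrations}.
#' @export
speciesFromChromatograms <- function(chroms,
                                     monomerWindow = c(31, 39),
                                     dimerWindow = c(22, 29),
                                     baseline = TRUE) {
  stopifnot(length(chroms) >= 1)
  rows <- lapply(chroms, function(ch) {
    stopifnot(is(ch, "Chromatogram"))
    ct <- ch@metadata$cTotal
    if (is.null(ct)) stop("chromatogram lacks metadata$cTotal")
    if (baseline) ch <- subtractBaseline(ch)
    pk <- quantifySpeciesPeaks(ch, monomerWindow, dimerWindow)
    c(areaM = pk$monomer@area, areaD = pk$dimer@area, cTotal = ct)
  })
  m <- do.call(rbind, rows)
  suppressWarnings(
    speciesFromAreas(m[, "areaM"], m[, "areaD"], m[, "cTotal"]))
}
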
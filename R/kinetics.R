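#' @include AllClasses.R
NULL

#' Initial rates from product time courses
#'
#' For each substrate concentration, the initial rate v0 (nmol/min) is the
#' ordinary least-squares slope of product (nmol) against time (min).
#'
#' @param dataset a \linkS4class{KineticsDataset} with at least 2 time
#'   points.
#' @return data.frame with columns \code{S} (mM), \code{v0} (nmol/min) and
#'   \code{se} (slope standard error; NA with 2 time points).
#' @export
initialRates <- function(dataset) {
  stopifnot(is(dataset, "KineticsDataset"))
  t <- dataset@times
  if (length(t) < 2) stop("need at least 2 time points per substrate")
  rows <- lapply(seq_along(dataset@substrate), function(i) {
    fit <- stats::lm(dataset@product[i, ] ~ t)
    co <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
    c(v0 = unname(co["t", "Estimate"]),
      se = if (length(t) > 2) unname(co["t", "Std. Error"]) else NA_real_)
  })
  m <- do.call(rbind, rows)
  data.frame(S = dataset@substrate, v0 = m[, "v0"], se = m[, "se"])
}

#' Fit the Michaelis-Menten equation
#'
#' Direct nonlinear least squares of \eqn{v_0 = V_{max}[S]/(K_m + [S])}
#' (no linearizing transform). \eqn{k_{cat}} is obtained from
#' \eqn{V_{max}} and the amount of enzyme in the assay
#' (\code{E0 * volume}); parameter sds come from the fit covariance and
#' the efficiency sd by first-order propagation including the
#' \eqn{V_{max}}-\eqn{K_m} covariance.
#'
#' @param rates either a \linkS4class{KineticsDataset} (initial rates are
#'   extracted first) or a data.frame with columns \code{S} (mM) and
#'   \code{v0} (nmol/min); needs >= 3 distinct substrate concentrations.
#' @param E0 enzyme concentration in the assay (uM); taken from the
#'   dataset when one is supplied.
#' @param reactionVolume assay volume (uL); likewise.
#' @return an \linkS4class{MMFit}.
#' @export
fitMichaelisMenten <- function(rates, E0 = 0.09, reactionVolume = 100) {
  if (is(rates, "KineticsDataset")) {
    E0 <- rates@E0
    reactionVolume <- rates@reactionVolume
    rates <- initialRates(rates)
  }
  stopifnot(all(c("S", "v0") %in% names(rates)))
  if (length(unique(rates$S)) < 3)
    stop("need at least 3 distinct substrate concentrations")
  if (any(rates$v0 < 0)) stop("negative initial rates")
  S <- rates$S; v0 <- rates$v0
  vmax0 <- max(v0) * 1.2
  km0 <- S[which.min(abs(v0 - max(v0) / 2))]
  fit <- minpack.lm::nlsLM(
    v0 ~ Vmax * S / (Km + S),
    start = list(Vmax = vmax0, Km = max(km0, 1e-6)),
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$convInfo$isConv)
    stop("Michaelis-Menten fit did not converge: ", fit$convInfo$stopMessage)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  enzymeNmol <- E0 * reactionVolume * 1e-3
  kcat <- cf[["Vmax"]] / enzymeNmol
  kmv <- cf[["Km"]]
  kcatSd <- sqrt(vc[1, 1]) / enzymeNmol
  kmSd <- sqrt(vc[2, 2])
  eff <- kcat / kmv
  # delta method: d(eff)/dVmax = 1/(E*Km), d(eff)/dKm = -Vmax/(E*Km^2)
  g <- c(1 / (enzymeNmol * kmv), -cf[["Vmax"]] / (enzymeNmol * kmv^2))
  effSd <- sqrt(drop(t(g) %*% vc %*% g))
  new("MMFit", kcat = kcat, kcatSd = kcatSd, km = kmv, kmSd = kmSd,
      efficiency = eff, efficiencySd = effSd, vmax = cf[["Vmax"]],
      rates = rates)
}

#' Catalytic efficiency relative to a reference enzyme
#'
#' \code{100 * efficiency / reference efficiency}, with sd propagated from
#' both fits (independent errors).
#'
#' @param fit,referenceFit \linkS4class{MMFit} objects.
#' @return named numeric: \code{relative} (\%) and \code{sd}.
#' @export
relativeEfficiency <- function(fit, referenceFit) {
  stopifnot(is(fit, "MMFit"), is(referenceFit, "MMFit"))
  if (referenceFit@efficiency <= 0) stop("reference efficiency must be positive")
  rel <- 100 * fit@efficiency / referenceFit@efficiency
  sd <- rel * sqrt((fit@efficiencySd / fit@efficiency)^2 +
                     (referenceFit@efficiencySd / referenceFit@efficiency)^2)
  c(relative = rel, sd = sd)
}
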
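#' @include structure.R
NULL

# Deterministic near-uniform unit sphere: golden-angle (Fibonacci) spiral.
# No RNG, so SASA values are reproducible bit-for-bit.
.spherePoints <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic probe-rolling SASA: each atom is inflated by the probe radius,
#' sampled with a deterministic golden-angle spiral of \code{nPoints}
#' points, and the accessible fraction is the share of sample points not
#' inside any neighbouring inflated sphere. Per-residue values are sums
#' over atoms. Accuracy improves as \code{nPoints} grows; 960 points keep
#' the isolated-sphere error well below 0.5\%.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param probe probe radius (A), default 1.4 (water).
#' @param nPoints sphere sample points per atom (>= 10).
#' @return list with \code{atom}: the atom table plus a \code{sasa}
#'   column (A^2); and \code{residue}: data.frame of per-residue sums
#'   (chain, resno, insert, resid, sasa).
#' @export
shrakeRupleySasa <- function(structure, probe = 1.4, nPoints = 960) {
  stopifnot(is(structure, "ProteinStructure"))
  if (nPoints < 10) stop("nPoints must be at least 10")
  if (probe < 0) stop("probe radius must be non-negative")
  a <- structure@atoms
  n <- nrow(a)
  xyz <- cbind(a$x, a$y, a$z)
  R <- a$radius + probe
  pts <- .spherePoints(nPoints)
  sasa <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    di <- xyz[, 1] - xyz[i, 1]
    dj <- xyz[, 2] - xyz[i, 2]
    dk <- xyz[, 3] - xyz[i, 3]
    d2 <- di * di + dj * dj + dk * dk
    nb <- which(d2 < (R[i] + maxR)^2 & d2 > 0)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    if (length(nb) == 0) {
      sasa[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dx <- p[free, 1] - xyz[j, 1]
      dy <- p[free, 2] - xyz[j, 2]
      dz <- p[free, 3] - xyz[j, 3]
      free[free] <- dx * dx + dy * dy + dz * dz >= R[j]^2
    }
    sasa[i] <- 4 * pi * R[i]^2 * sum(free) / nPoints
  }
  atom <- cbind(a, sasa = sasa)
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  agg <- rowsum(sasa, key)
  first <- !duplicated(key)
  residue <- data.frame(chain = a$chain[first], resno = a$resno[first],
                        insert = a$insert[first], resid = a$resid[first],
                        sasa = agg[match(key[first], rownames(agg)), 1],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(atom = atom, residue = residue)
}
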
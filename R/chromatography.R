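#' @include AllClasses.R
NULL

#' Construct a Chromatogram
#'
#' @param volume numeric, strictly increasing elution volumes (mL).
#' @param signal numeric detector trace (AU), same length.
#' @param metadata list of sample annotations (see
#'   \linkS4class{Chromatogram}).
#' @return a validated \linkS4class{Chromatogram}.
#' @export
chromatogram <- function(volume, signal, metadata = list()) {
  new("Chromatogram", volume = as.numeric(volume),
      signal = as.numeric(signal), metadata = metadata)
}

#' Read a chromatogram from CSV
#'
#' Expects a two-column numeric table (columns \code{volume_mL},
#' \code{signal_AU}; falling back to the first two columns when those names
#' are absent). If a YAML sidecar \code{<path>.yaml} (or the path with the
#' extension replaced by \code{.yaml}) exists, it is read into the
#' metadata; the key \code{c_total_uM} populates \code{metadata$cTotal}.
#'
#' Parse failures, a non-monotone volume axis and column-length problems
#' each raise a distinct error.
#'
#' @param path CSV file path.
#' @return a \linkS4class{Chromatogram}.
#' @export
readChromatogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("parse failure: ", conditionMessage(e)))
  if (ncol(df) < 2) stop("parse failure: need two columns")
  cols <- if (all(c("volume_mL", "signal_AU") %in% names(df)))
    c("volume_mL", "signal_AU") else names(df)[1:2]
  v <- suppressWarnings(as.numeric(df[[cols[1]]]))
  s <- suppressWarnings(as.numeric(df[[cols[2]]]))
  if (anyNA(v) || anyNA(s)) stop("parse failure: non-numeric values")
  if (length(v) != length(s)) stop("length mismatch between columns")
  if (any(diff(v) <= 0)) stop("non-monotone volume axis")
  meta <- list()
  side <- .sidecarPath(path)
  if (file.exists(side)) {
    y <- yaml::read_yaml(side)
    meta <- y
    if (!is.null(y$c_total_uM)) meta$cTotal <- y$c_total_uM
  }
  chromatogram(v, s, meta)
}

.sidecarPath <- function(path) sub("\\.[Cc][Ss][Vv]$", ".yaml", path)

#' Write a chromatogram to CSV (plus YAML sidecar)
#'
#' Writes columns \code{volume_mL}, \code{signal_AU}; sample metadata
#' (total concentration, buffer, sample id) goes to a YAML sidecar next to
#' the CSV.
#'
#' @param chrom a \linkS4class{Chromatogram}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeChromatogram <- function(chrom, path) {
  stopifnot(is(chrom, "Chromatogram"))
  # 17 significant digits so numeric round-trip is exact
  utils::write.csv(
    data.frame(volume_mL = sprintf("%.17g", chrom@volume),
               signal_AU = sprintf("%.17g", chrom@signal)),
    path, row.names = FALSE, quote = FALSE)
  meta <- chrom@metadata
  side <- list(c_total_uM = meta$cTotal, buffer = meta$buffer,
               sample_id = meta$sampleId, temperature_C = meta$temperature)
  side <- side[!vapply(side, is.null, logical(1))]
  if (length(side)) yaml::write_yaml(side, .sidecarPath(path))
  invisible(path)
}

#' Subtract a linear baseline
#'
#' Fits the line through the mean (volume, signal) of the first and last
#' \code{k} points and subtracts it. On a trace whose ends sit on the
#' baseline this leaves peak areas unchanged; the operation is exactly
#' idempotent.
#'
#' @param chrom a \linkS4class{Chromatogram} with at least 2 points.
#' @param method baseline model; only \code{"linear-endpoints"} is
#'   implemented.
#' @param k number of points averaged at each end.
#' @return a baseline-corrected \linkS4class{Chromatogram}.
#' @export
subtractBaseline <- function(chrom, method = "linear-endpoints", k = 5) {
  stopifnot(is(chrom, "Chromatogram"))
  method <- match.arg(method, "linear-endpoints")
  n <- length(chrom@volume)
  if (n < 2) stop("need at least 2 points")
  k <- min(k, floor(n / 2))
  i1 <- seq_len(k); i2 <- seq(n - k + 1, n)
  v1 <- mean(chrom@volume[i1]); s1 <- mean(chrom@signal[i1])
  v2 <- mean(chrom@volume[i2]); s2 <- mean(chrom@signal[i2])
  slope <- (s2 - s1) / (v2 - v1)
  base <- s1 + slope * (chrom@volume - v1)
  chromatogram(chrom@volume, chrom@signal - base, chrom@metadata)
}

#' Integrate the dimer and monomer peaks
#'
#' Trapezoidal integration of the signal over two fixed, disjoint volume
#' windows -- the approach used when the two species are known and well
#' separated. Default windows are 22-29 mL (dimer) and 31-39 mL (monomer).
#' Small negative areas arising from noise are clipped at zero.
#'
#' @param chrom a \linkS4class{Chromatogram}.
#' @param monomerWindow,dimerWindow numeric(2) windows (mL); must be
#'   disjoint and inside the volume range.
#' @return list with components \code{dimer} and \code{monomer}, each a
#'   \linkS4class{Peak}.
#' @export
quantifySpeciesPeaks <- function(chrom,
                                 monomerWindow = c(31, 39),
                                 dimerWindow = c(22, 29)) {
  stopifnot(is(chrom, "Chromatogram"))
  .checkWindow <- function(w, nm) {
    if (length(w) != 2 || w[1] >= w[2]) stop(nm, " must be (lo, hi) with lo < hi")
    if (w[1] < min(chrom@volume) || w[2] > max(chrom@volume))
      stop(nm, " outside the recorded volume range")
  }
  .checkWindow(monomerWindow, "monomerWindow")
  .checkWindow(dimerWindow, "dimerWindow")
  if (max(dimerWindow[1], monomerWindow[1]) <
      min(dimerWindow[2], monomerWindow[2]))
    stop("integration windows overlap")
  .integrate <- function(w) {
    idx <- which(chrom@volume >= w[1] & chrom@volume <= w[2])
    if (length(idx) < 2) stop("fewer than 2 points inside window")
    v <- chrom@volume[idx]; s <- chrom@signal[idx]
    area <- max(0, pracma::trapz(v, s))
    # apex restricted to the window interior so lo < apex < hi always holds
    interior <- if (length(idx) > 2) 2:(length(idx) - 1) else seq_along(idx)
    apex <- v[interior][which.max(s[interior])]
    apex <- min(max(apex, w[1] + 1e-9), w[2] - 1e-9)
    new("Peak", lo = w[1], hi = w[2], apex = apex, area = area)
  }
  list(dimer = .integrate(dimerWindow), monomer = .integrate(monomerWindow))
}
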
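# shared helpers for the test suite

# Reference per-atom SASA for the synthetic pentapeptide fixture, computed
# with Biopython's Shrake-Rupley (n_points = 960, probe 1.4 A, radii
# C 1.70 / N 1.55 / O 1.52 / S 1.80) on the same file.
.refPentapeptideSasa <- c(
  55.8186, 41.3864, 11.5731, 27.7910,                     # GLY 1
  8.2019, 10.9441, 5.9123, 25.1123, 54.7207,              # ALA 2
  5.2401, 6.0381, 1.8869, 23.8846, 31.4487, 43.8629,      # SER 3
  5.3540, 10.6925, 4.7802, 20.8711, 3.6480, 46.2924, 50.4436,  # VAL 4
  1.7087, 6.1639, 23.6494, 50.4479, 16.7307, 5.6608, 52.9595, 56.3560)  # LEU 5

logGrid <- function(lo, hi, n) 10^seq(log10(lo), log10(hi), length.out = n)

extdata <- function(name) {
  path <- system.file("extdata", name, package = "SECdimer")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

# a one-atom structure (element C unless overridden)
singleAtom <- function(radius = 1.5, element = "C", elety = "CB",
                       resid = "ALA", x = 0, y = 0, z = 0) {
  proteinStructure(data.frame(
    chain = "A", resno = 1L, resid = resid, elety = elety,
    element = element, x = x, y = y, z = z, radius = radius,
    stringsAsFactors = FALSE))
}

# an n-atom structure from a coordinate matrix
atomsAt <- function(xyz, element = "C", radius = 1.5, chain = "A",
                    resid = "ALA", elety = NULL) {
  n <- nrow(xyz)
  if (is.null(elety)) elety <- rep("CB", n)
  proteinStructure(data.frame(
    chain = rep_len(chain, n), resno = seq_len(n),
    resid = rep_len(resid, n), elety = elety,
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep_len(radius, n), stringsAsFactors = FALSE))
}
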
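# Element van der Waals radii (Angstrom); a deliberately small fixed table.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Theoretical maximum accessible surface area (Angstrom^2) per residue in a
# Gly-X-Gly tripeptide (Tien et al. 2013), used to normalize residue SASA.
.MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Near-uniform points on the unit sphere (golden-spiral construction).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per residue (Shrake-Rupley)
#'
#' Computes atomic SASA by spherical quadrature: each atom's sphere is
#' expanded by the probe radius and covered with near-uniform test points;
#' the accessible fraction is the share of points falling inside no other
#' expanded sphere, and atomic areas are summed per residue. The default
#' probe radius of 1.4 Angstrom is the conventional water probe.
#'
#' @param model a non-empty [ProteinModel-class].
#' @param probeRadius solvent probe radius in Angstrom, >= 0 (default 1.4).
#' @param nSpherePoints quadrature points per atom, >= 60 (default 960).
#' @return named numeric vector: residue index -> SASA in Angstrom^2.
#' @examples
#' m <- generateToyStructure(10, seed = 1)
#' sasaPerResidue(m)
#' @export
sasaPerResidue <- function(model, probeRadius = 1.4, nSpherePoints = 960) {
  stopifnot(is(model, "ProteinModel"))
  at <- model@atoms
  if (nrow(at) == 0L) stop("model has no atoms")
  if (probeRadius < 0) stop("probeRadius must be >= 0")
  if (nSpherePoints < 60) stop("nSpherePoints must be >= 60")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$radius + probeRadius
  unitPts <- .spherePoints(as.integer(nSpherePoints))
  n <- nrow(at)
  atomArea <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < R[i] + R & seq_len(n) != i)
    frac <- if (length(nb) == 0L) 1 else {
      pts <- unitPts * R[i]
      pts <- sweep(pts, 2, xyz[i, ], "+")
      buried <- rep(FALSE, nrow(pts))
      for (j in nb)
        buried <- buried | (rowSums(sweep(pts, 2, xyz[j, ])^2) < R[j]^2)
      mean(!buried)
    }
    atomArea[i] <- frac * 4 * pi * R[i]^2
  }
  res <- tapply(atomArea, at$resno, sum)
  setNames(as.numeric(res), names(res))
}

#' Percent solvent accessibility of a residue
#'
#' Normalizes a residue's SASA by the theoretical maximum accessible surface
#' area of that amino acid in an extended Gly-X-Gly context, giving the
#' percent exposure used to distinguish buried from surface positions.
#' Values above the reference (possible for termini or unusual geometry) are
#' clamped to 100.
#'
#' @param residueSasa SASA in Angstrom^2, >= 0; vectorized.
#' @param residueName 3-letter amino acid code(s), case-insensitive.
#' @return percent in [0, 100].
#' @examples
#' relativeSasa(64.5, "ALA")   # 50
#' relativeSasa(300, "GLY")    # clamped to 100
#' @export
relativeSasa <- function(residueSasa, residueName) {
  if (any(is.na(residueSasa)) || any(residueSasa < 0))
    stop("residueSasa must be >= 0")
  ref <- .MAX_ASA[toupper(residueName)]
  if (any(is.na(ref)))
    stop("unknown residue name: ",
         paste(unique(residueName[is.na(ref)]), collapse = ", "))
  pmin(100, 100 * residueSasa / unname(ref))
}

#' Steric clash score (overlaps per 1000 atoms)
#'
#' Counts unordered pairs of non-bonded atoms whose van der Waals spheres
#' interpenetrate by at least \code{overlapCutoff} Angstrom
#' (r_i + r_j - d_ij >= cutoff), scaled per 1000 atoms. Pairs within the same
#' or consecutive residues are excluded as covalently bonded or near-bonded
#' proxies. This is an overlap-counting simplification of dot-based
#' clashscores: a structure-quality signal, not a replacement for full
#' all-atom contact analysis.
#'
#' @param model a non-empty [ProteinModel-class].
#' @param overlapCutoff overlap threshold in Angstrom, > 0 (default 0.4).
#' @return clashes per 1000 atoms.
#' @examples
#' clashScore(generateToyStructure(20, seed = 1))  # 0 for the ideal helix
#' @export
clashScore <- function(model, overlapCutoff = 0.4) {
  stopifnot(is(model, "ProteinModel"))
  at <- model@atoms
  if (nrow(at) == 0L) stop("model has no atoms")
  if (overlapCutoff <= 0) stop("overlapCutoff must be > 0")
  n <- nrow(at)
  if (n < 2L) return(0)
  d <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
  sumR <- outer(at$radius, at$radius, "+")
  sepRes <- abs(outer(at$resno, at$resno, "-")) >= 2
  clash <- (sumR - d >= overlapCutoff) & sepRes & upper.tri(d)
  1000 * sum(clash) / n
}

#' Bin a model-confidence score
#'
#' Maps per-residue confidence in [0, 100] to the four reporting bins
#' \code{"<50"}, \code{"50-70"}, \code{"70-90"}, \code{">90"}. Boundary
#' convention: 50 and 70 belong to the higher bin of each pair, 90 belongs
#' to \code{"70-90"} (so \code{">90"} is strict).
#'
#' @param score numeric in [0, 100]; vectorized.
#' @return character bin labels.
#' @examples
#' binConfidence(c(49.9, 50, 70, 90, 90.1))
#' @export
binConfidence <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 100))
    stop("score must lie in [0, 100]")
  ifelse(score < 50, "<50",
         ifelse(score < 70, "50-70",
                ifelse(score <= 90, "70-90", ">90")))
}

#' Test whether a residue position falls inside a domain annotation
#'
#' @param position 1-based residue index (>= 1); vectorized.
#' @param track a [DomainTrack-class] (0-based half-open intervals).
#' @return logical: TRUE where \code{position - 1} lies in some interval.
#' @examples
#' tr <- domainTrack(0, 10)
#' inDomain(c(1, 10, 11), tr)   # TRUE TRUE FALSE
#' @export
inDomain <- function(position, track) {
  stopifnot(is(track, "DomainTrack"))
  if (any(is.na(position)) || any(position < 1))
    stop("position must be >= 1")
  iv <- track@intervals
  if (nrow(iv) == 0L) return(rep(FALSE, length(position)))
  p0 <- position - 1
  vapply(p0, function(p) any(p >= iv[, 1] & p < iv[, 2]), logical(1))
}
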
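.CLASS_LEVELS <- c("B", "LB", "LP", "P", "VUS")

#' Class-conditional score profile for one classification level
#'
#' A \code{ClassProfile} describes how variants of one classification level
#' (B, LB, LP, P or VUS) are distributed: how many there are, the
#' bivariate-normal parameters of their (ddG_Fold, CADD) score pairs, and the
#' multinomial probabilities of the four per-residue model-confidence bins
#' (<50, 50-70, 70-90, >90).
#'
#' @slot label classification level, one of \code{"B"}, \code{"LB"},
#'   \code{"LP"}, \code{"P"}, \code{"VUS"}.
#' @slot count number of variants of this class in the cohort.
#' @slot ddgMean,ddgSd mean and SD of the folding free energy difference
#'   (kcal/mol; positive destabilizes).
#' @slot caddMean,caddSd mean and SD of the scaled CADD score.
#' @slot rho correlation between ddG_Fold and CADD, in (-1, 1).
#' @slot confBinProbs probabilities of the four model-confidence bins, in the
#'   order <50, 50-70, 70-90, >90; must sum to 1.
#'
#' @seealso [classProfile()], [defaultCohortConfig()]
#' @export
setClass("ClassProfile",
  representation(
    label = "character",
    count = "numeric",
    ddgMean = "numeric",
    ddgSd = "numeric",
    caddMean = "numeric",
    caddSd = "numeric",
    rho = "numeric",
    confBinProbs = "numeric"
  )
)

setValidity("ClassProfile", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !object@label %in% .CLASS_LEVELS)
    msg <- c(msg, sprintf("label must be one of %s",
                          paste(.CLASS_LEVELS, collapse = ", ")))
  if (length(object@count) != 1L || is.na(object@count) ||
      object@count < 0 || object@count != round(object@count))
    msg <- c(msg, "count must be a single non-negative integer")
  if (object@ddgSd <= 0) msg <- c(msg, "ddgSd must be > 0")
  if (object@caddSd <= 0) msg <- c(msg, "caddSd must be > 0")
  if (abs(object@rho) >= 1) msg <- c(msg, "rho must satisfy |rho| < 1")
  if (length(object@confBinProbs) != 4L || any(object@confBinProbs < 0) ||
      abs(sum(object@confBinProbs) - 1) > 1e-9)
    msg <- c(msg, "confBinProbs must be 4 non-negative values summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ClassProfile
#'
#' @param label classification level (B, LB, LP, P, VUS).
#' @param count non-negative integer number of variants.
#' @param ddgMean,ddgSd ddG_Fold distribution parameters (kcal/mol).
#' @param caddMean,caddSd CADD distribution parameters.
#' @param rho ddG/CADD correlation in (-1, 1).
#' @param confBinProbs probabilities for confidence bins <50, 50-70, 70-90,
#'   >90 (summing to 1).
#' @return a [ClassProfile-class] object.
#' @examples
#' classProfile("P", 100, ddgMean = 0.8, ddgSd = 1.0,
#'              caddMean = 26, caddSd = 3, rho = 0.4,
#'              confBinProbs = c(0.2, 0.1, 0.3, 0.4))
#' @export
classProfile <- function(label, count, ddgMean, ddgSd, caddMean, caddSd,
                         rho, confBinProbs) {
  new("ClassProfile", label = label, count = as.numeric(count),
      ddgMean = ddgMean, ddgSd = ddgSd, caddMean = caddMean,
      caddSd = caddSd, rho = rho, confBinProbs = confBinProbs)
}

#' Synthetic cohort configuration
#'
#' Bundles the per-class [ClassProfile-class] set, the latent composition of
#' the VUS class, and the gene catalog used to assign variants to proteins.
#' VUS score pairs are drawn from a two-component mixture: with probability
#' \code{vusPathogenicFraction} from the P-class distribution, otherwise from
#' the B-class distribution, modelling the unknown composition of VUSs.
#'
#' @slot profiles list of [ClassProfile-class] objects, one per class.
#' @slot vusPathogenicFraction probability in [0, 1] that a VUS score pair is
#'   drawn from the pathogenic-class distribution.
#' @slot geneCatalog data.frame with columns \code{gene} and \code{length}
#'   (protein length in amino acids, >= 1).
#'
#' @seealso [defaultCohortConfig()], [generateVariantTable()]
#' @export
setClass("CohortConfig",
  representation(
    profiles = "list",
    vusPathogenicFraction = "numeric",
    geneCatalog = "data.frame"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@profiles, is, logical(1), "ClassProfile")))
    msg <- c(msg, "profiles must all be ClassProfile objects")
  labs <- vapply(object@profiles, function(p) p@label, character(1))
  if (anyDuplicated(labs))
    msg <- c(msg, "duplicate class labels in profiles")
  f <- object@vusPathogenicFraction
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    msg <- c(msg, "vusPathogenicFraction must be in [0, 1]")
  gc <- object@geneCatalog
  if (!all(c("gene", "length") %in% names(gc)))
    msg <- c(msg, "geneCatalog needs columns 'gene' and 'length'")
  else if (nrow(gc) > 0 && any(gc$length < 1))
    msg <- c(msg, "gene lengths must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Thermodynamic parameters
#'
#' Gas constant and absolute temperature used to convert folding free energy
#' differences into equilibrium-ratio changes. Defaults are standard
#' conditions: R = 1.987e-3 kcal/(mol K), T = 298.15 K.
#'
#' @slot gasConstant kcal/(mol K).
#' @slot temperature Kelvin.
#' @seealso [foldRatioChange()], [ddgForFoldDecrease()]
#' @export
setClass("ThermoParams",
  representation(gasConstant = "numeric", temperature = "numeric"),
  prototype(gasConstant = 1.987e-3, temperature = 298.15)
)

setValidity("ThermoParams", function(object) {
  if (length(object@gasConstant) != 1L || object@gasConstant <= 0)
    return("gasConstant must be a single positive number")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    return("temperature must be a single positive number")
  TRUE
})

#' @param gasConstant kcal/(mol K); default 1.987e-3.
#' @param temperature Kelvin; default 298.15.
#' @rdname ThermoParams-class
#' @examples
#' thermoParams()                      # standard conditions
#' thermoParams(temperature = 310.15)  # physiological
#' @export
thermoParams <- function(gasConstant = 1.987e-3, temperature = 298.15) {
  new("ThermoParams", gasConstant = gasConstant, temperature = temperature)
}

#' Joint score threshold rule
#'
#' A rule over (ddG_Fold, CADD) score pairs. A variant passes when every
#' cutoff that is present is exceeded strictly. With
#' \code{direction = "destabilizing"} (the default) the stability condition is
#' \code{ddg_fold > ddgCutoff}; with \code{direction = "overstabilizing"} it is
#' \code{ddg_fold < -ddgCutoff}, supporting the analysis of strongly
#' stabilizing variants. The CADD condition is always \code{cadd > caddCutoff}.
#'
#' @slot ddgCutoff kcal/mol, or NA when the rule has no stability condition.
#' @slot caddCutoff CADD scale, or NA when the rule has no CADD condition.
#' @slot direction \code{"destabilizing"} or \code{"overstabilizing"}.
#' @seealso [thresholdRule()], [evaluateRule()], [prioritizeVariants()]
#' @export
setClass("ThresholdRule",
  representation(
    ddgCutoff = "numeric",
    caddCutoff = "numeric",
    direction = "character"
  ),
  prototype(ddgCutoff = NA_real_, caddCutoff = NA_real_,
            direction = "destabilizing")
)

setValidity("ThresholdRule", function(object) {
  msg <- character()
  if (is.na(object@ddgCutoff) && is.na(object@caddCutoff))
    msg <- c(msg, "at least one cutoff must be present")
  if (!is.na(object@ddgCutoff) && !is.finite(object@ddgCutoff))
    msg <- c(msg, "ddgCutoff must be finite or NA")
  if (!is.na(object@caddCutoff) && !is.finite(object@caddCutoff))
    msg <- c(msg, "caddCutoff must be finite or NA")
  if (!object@direction %in% c("destabilizing", "overstabilizing"))
    msg <- c(msg, "direction must be 'destabilizing' or 'overstabilizing'")
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdRule
#'
#' @param ddgCutoff ddG_Fold cutoff in kcal/mol (NA to omit).
#' @param caddCutoff CADD cutoff (NA to omit). At least one cutoff is needed.
#' @param direction \code{"destabilizing"} (pass iff ddg > cutoff) or
#'   \code{"overstabilizing"} (pass iff ddg < -cutoff).
#' @return a [ThresholdRule-class].
#' @examples
#' thresholdRule(1.8, 25.7)         # the joint prioritization rule
#' thresholdRule(1.8)               # stability-only
#' thresholdRule(1.8, direction = "overstabilizing")
#' @export
thresholdRule <- function(ddgCutoff = NA_real_, caddCutoff = NA_real_,
                          direction = c("destabilizing", "overstabilizing")) {
  new("ThresholdRule", ddgCutoff = as.numeric(ddgCutoff),
      caddCutoff = as.numeric(caddCutoff), direction = match.arg(direction))
}

#' Confusion-matrix summary of a threshold rule
#'
#' Counts of true/false positives and negatives from evaluating a
#' [ThresholdRule-class] against expert classifications, with derived rates
#' available through [ppv()], [npv()], [sensitivity()] and [specificity()].
#' A rate whose denominator is zero is reported as \code{NA}.
#'
#' @slot tp,fp,tn,fn integer counts.
#' @seealso [evaluateRule()]
#' @export
setClass("ConfusionSummary",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer")
)

setValidity("ConfusionSummary", function(object) {
  counts <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(counts)) || any(counts < 0))
    return("tp, fp, tn, fn must be non-negative counts")
  TRUE
})

#' Protein structural model
#'
#' A minimal atomic model: heavy-atom (or hydrogen) records with element, van
#' der Waals radius, Cartesian coordinates and residue assignment, plus a
#' per-residue model-confidence score in [0, 100] (the pLDDT convention of
#' predicted structures, stored in the PDB B-factor column on disk).
#'
#' @slot atoms data.frame with columns \code{element}, \code{radius} (vdW, in
#'   Angstrom), \code{x}, \code{y}, \code{z} (Angstrom), \code{resno}
#'   (1-based, contiguous), \code{resid} (3-letter residue name), \code{name}
#'   (atom name).
#' @slot confidence numeric vector, one score in [0, 100] per residue, named
#'   by residue index.
#' @seealso [readProteinModel()], [generateToyStructure()], [sasaPerResidue()]
#' @export
setClass("ProteinModel",
  representation(atoms = "data.frame", confidence = "numeric")
)

setValidity("ProteinModel", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("element", "radius", "x", "y", "z", "resno", "resid", "name")
  if (!all(need %in% names(at)))
    return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
  if (nrow(at) > 0) {
    if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
      msg <- c(msg, "coordinates must be finite")
    if (any(!is.finite(at$radius)) || any(at$radius <= 0))
      msg <- c(msg, "vdW radii must be positive")
    res <- sort(unique(at$resno))
    if (!isTRUE(all.equal(as.numeric(res), as.numeric(seq_along(res)))))
      msg <- c(msg, "residue indices must be contiguous from 1")
    if (length(object@confidence) != length(res))
      msg <- c(msg, "confidence must have one value per residue")
    else if (any(object@confidence < 0 | object@confidence > 100))
      msg <- c(msg, "confidence scores must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Protein domain annotation track
#'
#' Half-open intervals [start, end) on 0-based protein residue coordinates
#' (the BED convention). Intervals are normalized on construction: sorted and
#' overlapping/adjacent intervals merged.
#'
#' @slot intervals two-column matrix (start, end), 0-based half-open.
#' @seealso [domainTrack()], [inDomain()], [readDomainBed()]
#' @export
setClass("DomainTrack", representation(intervals = "matrix"))

setValidity("DomainTrack", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns")
  if (nrow(iv) == 0L) return(TRUE)
  if (any(iv[, 1] >= iv[, 2])) return("each interval needs start < end")
  if (is.unsorted(iv[, 1], strictly = TRUE) ||
      any(iv[-1, 1] < iv[-nrow(iv), 2]))
    return("intervals must be sorted and non-overlapping")
  TRUE
})

#' Construct a DomainTrack
#'
#' @param starts,ends 0-based half-open interval bounds on protein residue
#'   coordinates (BED convention). Overlapping or book-ended intervals are
#'   merged.
#' @return a [DomainTrack-class].
#' @examples
#' domainTrack(c(0, 5), c(10, 20))   # merges to [0, 20)
#' @export
domainTrack <- function(starts = numeric(), ends = numeric()) {
  if (length(starts) != length(ends))
    stop("starts and ends must have the same length")
  if (any(starts >= ends)) stop("each interval needs start < end")
  if (length(starts) == 0L)
    return(new("DomainTrack",
               intervals = matrix(numeric(), 0, 2,
                                  dimnames = list(NULL, c("start", "end")))))
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  ms <- s[1]; me <- e[1]; out <- NULL
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out <- rbind(out, c(ms, me)); ms <- s[i]; me <- e[i] }
  }
  out <- rbind(out, c(ms, me))
  colnames(out) <- c("start", "end")
  new("DomainTrack", intervals = out)
}
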
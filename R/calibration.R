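.checkVariants <- function(variants) {
  need <- c("classification", "ddg_fold", "cadd")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(variants$classification), .CLASS_LEVELS)
  if (length(bad))
    stop("unknown classification label(s): ", paste(bad, collapse = ", "))
  invisible(variants)
}

#' Which variants pass a threshold rule
#'
#' A variant passes when every cutoff present in the rule is exceeded
#' strictly: \code{ddg_fold > ddgCutoff} (or \code{ddg_fold < -ddgCutoff} for
#' an overstabilizing rule) and \code{cadd > caddCutoff}. Missing scores fail
#' the corresponding condition.
#'
#' @param variants variant data.frame (see [readVariantTable()] for the
#'   schema).
#' @param rule a [ThresholdRule-class].
#' @return logical vector along the rows of \code{variants}.
#' @export
rulePass <- function(variants, rule) {
  stopifnot(is(rule, "ThresholdRule"))
  validObject(rule)
  pass <- rep(TRUE, nrow(variants))
  if (!is.na(rule@ddgCutoff)) {
    d <- variants$ddg_fold
    ok <- if (rule@direction == "destabilizing") d > rule@ddgCutoff
          else d < -rule@ddgCutoff
    pass <- pass & !is.na(d) & ok
  }
  if (!is.na(rule@caddCutoff)) {
    cd <- variants$cadd
    pass <- pass & !is.na(cd) & (cd > rule@caddCutoff)
  }
  pass
}

#' Evaluate a threshold rule against expert classifications
#'
#' Restricts the table to the positive and negative classification sets,
#' applies the rule, and tallies the confusion matrix: TP = positives
#' passing, FP = negatives passing, FN/TN their complements. Variants outside
#' both sets are ignored. With the calibrated synthetic cohort, the
#' stability-only rule ddG_Fold > 1.8 kcal/mol recovers a PPV near 97.1% and
#' specificity near 98.2% for positives = P against negatives = B.
#'
#' @inheritParams rulePass
#' @param positiveClasses,negativeClasses disjoint sets of classification
#'   labels; defaults \code{"P"} and \code{"B"}.
#' @return a [ConfusionSummary-class].
#' @examples
#' v <- data.frame(classification = c("P", "P", "B", "B"),
#'                 ddg_fold = c(2.5, 0.3, 2.0, -0.1),
#'                 cadd = c(30, 22, 18, 10))
#' evaluateRule(v, thresholdRule(1.8))
#' @export
evaluateRule <- function(variants, rule,
                         positiveClasses = "P", negativeClasses = "B") {
  .checkVariants(variants)
  if (length(intersect(positiveClasses, negativeClasses)))
    stop("positive and negative class sets must be disjoint")
  pos <- variants$classification %in% positiveClasses
  neg <- variants$classification %in% negativeClasses
  pass <- rulePass(variants, rule)
  new("ConfusionSummary",
      tp = sum(pos & pass), fp = sum(neg & pass),
      tn = sum(neg & !pass), fn = sum(pos & !pass))
}

#' Smallest CADD cutoff reaching a target PPV on top of a ddG cutoff
#'
#' Candidate cutoffs are the sorted unique CADD values of classified
#' (positive- or negative-set) variants that pass the ddG_Fold cutoff. The
#' function returns the smallest candidate c for which the joint rule
#' \code{ddg_fold > ddgCutoff & cadd > c} achieves PPV >= \code{targetPpv};
#' \code{NA} if no candidate attains the target or no classified variant
#' passes the ddG cutoff. This is the search that, on the published cohort,
#' sets the CADD threshold to 25.7 for a 99% PPV.
#'
#' @inheritParams evaluateRule
#' @param ddgCutoff ddG_Fold cutoff in kcal/mol.
#' @param targetPpv required positive predictive value in (0, 1].
#' @return numeric CADD cutoff, or \code{NA_real_} on failure.
#' @examples
#' v <- data.frame(classification = c("P", "P", "P", "B", "B"),
#'                 ddg_fold = c(2.0, 2.5, 1.0, 2.0, 0.5),
#'                 cadd = c(30, 20, 40, 26, 35))
#' findCaddCutoff(v, 1.8, 1.0)   # 26
#' @export
findCaddCutoff <- function(variants, ddgCutoff, targetPpv,
                           positiveClasses = "P", negativeClasses = "B") {
  .checkVariants(variants)
  if (!(targetPpv > 0 && targetPpv <= 1))
    stop("targetPpv must be in (0, 1]")
  cl <- variants$classification %in% c(positiveClasses, negativeClasses)
  ddgPass <- rulePass(variants, thresholdRule(ddgCutoff))
  pool <- variants[cl & ddgPass, , drop = FALSE]
  if (nrow(pool) == 0L) return(NA_real_)
  candidates <- sort(unique(pool$cadd[!is.na(pool$cadd)]))
  for (c in candidates) {
    cs <- evaluateRule(variants, thresholdRule(ddgCutoff, c),
                       positiveClasses, negativeClasses)
    p <- ppv(cs)
    if (!is.na(p) && p >= targetPpv) return(c)
  }
  NA_real_
}

#' Confusion-matrix sweep over a cutoff grid
#'
#' Evaluates every (ddG cutoff, CADD cutoff) pair on a grid and tabulates the
#' confusion counts and derived rates, supporting threshold-exploration plots
#' and alternative operating points (e.g. relaxing the stability cutoff to
#' 1.0 kcal/mol while dropping the CADD condition).
#'
#' @inheritParams evaluateRule
#' @param ddgGrid,caddGrid non-empty numeric cutoff vectors; use
#'   \code{NA} within \code{caddGrid} for ddG-only rules.
#' @return data.frame with one row per grid pair (ddG-major, CADD-minor
#'   order) and columns \code{ddg_cutoff}, \code{cadd_cutoff}, \code{tp},
#'   \code{fp}, \code{tn}, \code{fn}, \code{ppv}, \code{npv},
#'   \code{sensitivity}, \code{specificity}.
#' @export
sweepThresholds <- function(variants, ddgGrid, caddGrid,
                            positiveClasses = "P", negativeClasses = "B") {
  if (length(ddgGrid) == 0L || length(caddGrid) == 0L)
    stop("grids must be non-empty")
  grid <- expand.grid(cadd_cutoff = caddGrid, ddg_cutoff = ddgGrid,
                      KEEP.OUT.ATTRS = FALSE)[, 2:1]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cs <- evaluateRule(variants,
                       thresholdRule(grid$ddg_cutoff[i], grid$cadd_cutoff[i]),
                       positiveClasses, negativeClasses)
    data.frame(grid[i, ], tp = truePositives(cs), fp = falsePositives(cs),
               tn = trueNegatives(cs), fn = falseNegatives(cs),
               ppv = ppv(cs), npv = npv(cs),
               sensitivity = sensitivity(cs), specificity = specificity(cs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reclassify common variants of uncertain significance as likely benign
#'
#' VUS rows whose minor allele frequency exceeds \code{mafCutoff} are
#' relabeled LB (common variants are unlikely to cause rare disease); other
#' classes and rows with missing MAF are untouched. A provenance column
#' \code{maf_reclassified} records which rows changed.
#'
#' @inheritParams evaluateRule
#' @param mafCutoff MAF threshold in [0, 1] (default 0.005).
#' @return the variant data.frame with updated \code{classification} and a
#'   logical \code{maf_reclassified} column.
#' @export
mafFilter <- function(variants, mafCutoff = 0.005) {
  .checkVariants(variants)
  if (is.na(mafCutoff) || mafCutoff < 0 || mafCutoff > 1)
    stop("mafCutoff must be in [0, 1]")
  hit <- if (is.null(variants$maf)) rep(FALSE, nrow(variants))
         else variants$classification == "VUS" &
              !is.na(variants$maf) & variants$maf > mafCutoff
  variants$classification[hit] <- "LB"
  variants$maf_reclassified <- hit
  variants
}
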
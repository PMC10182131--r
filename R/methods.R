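.safeRate <- function(num, den) if (den == 0L) NA_real_ else num / den

#' @rdname confusion-accessors
setMethod("ppv", "ConfusionSummary",
          function(x) .safeRate(x@tp, x@tp + x@fp))
#' @rdname confusion-accessors
setMethod("npv", "ConfusionSummary",
          function(x) .safeRate(x@tn, x@tn + x@fn))
#' @rdname confusion-accessors
setMethod("sensitivity", "ConfusionSummary",
          function(x) .safeRate(x@tp, x@tp + x@fn))
#' @rdname confusion-accessors
setMethod("specificity", "ConfusionSummary",
          function(x) .safeRate(x@tn, x@tn + x@fp))
#' @rdname confusion-accessors
setMethod("truePositives", "ConfusionSummary", function(x) x@tp)
#' @rdname confusion-accessors
setMethod("falsePositives", "ConfusionSummary", function(x) x@fp)
#' @rdname confusion-accessors
setMethod("trueNegatives", "ConfusionSummary", function(x) x@tn)
#' @rdname confusion-accessors
setMethod("falseNegatives", "ConfusionSummary", function(x) x@fn)

#' @rdname model-accessors
setMethod("nAtoms", "ProteinModel", function(x) nrow(x@atoms))
#' @rdname model-accessors
setMethod("nResidues", "ProteinModel",
          function(x) length(unique(x@atoms$resno)))
#' @rdname model-accessors
setMethod("atomTable", "ProteinModel", function(x) x@atoms)
#' @rdname model-accessors
setMethod("residueConfidence", "ProteinModel", function(x) x@confidence)

.fmtPct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)

setMethod("show", "ConfusionSummary", function(object) {
  cat("ConfusionSummary\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  PPV %s  NPV %s  sensitivity %s  specificity %s\n",
              .fmtPct(ppv(object)), .fmtPct(npv(object)),
              .fmtPct(sensitivity(object)), .fmtPct(specificity(object))))
})

setMethod("show", "ThresholdRule", function(object) {
  parts <- character()
  if (!is.na(object@ddgCutoff))
    parts <- c(parts,
               if (object@direction == "destabilizing")
                 sprintf("ddG_Fold > %g kcal/mol", object@ddgCutoff)
               else sprintf("ddG_Fold < %g kcal/mol", -object@ddgCutoff))
  if (!is.na(object@caddCutoff))
    parts <- c(parts, sprintf("CADD > %g", object@caddCutoff))
  cat("ThresholdRule:", paste(parts, collapse = " AND "), "\n")
})

setMethod("show", "ProteinModel", function(object) {
  cat(sprintf("ProteinModel: %d atoms, %d residues\n",
              nAtoms(object), nResidues(object)))
  if (nResidues(object) > 0)
    cat(sprintf("  confidence range [%.1f, %.1f]\n",
                min(object@confidence), max(object@confidence)))
})

setMethod("show", "ClassProfile", function(object) {
  cat(sprintf(
    "ClassProfile %s: n=%d, ddG ~ N(%.3g, %.3g), CADD ~ N(%.3g, %.3g), rho=%.2g\n",
    object@label, object@count, object@ddgMean, object@ddgSd,
    object@caddMean, object@caddSd, object@rho))
})

setMethod("show", "CohortConfig", function(object) {
  labs <- vapply(object@profiles, function(p) p@label, character(1))
  n <- vapply(object@profiles, function(p) p@count, numeric(1))
  cat(sprintf("CohortConfig: %d classes, %d variants total\n",
              length(labs), sum(n)))
  cat("  ", paste(sprintf("%s=%d", labs, n), collapse = "  "), "\n")
  cat(sprintf("  VUS pathogenic mixture fraction: %.2f; %d genes\n",
              object@vusPathogenicFraction, nrow(object@geneCatalog)))
})

setMethod("show", "DomainTrack", function(object) {
  cat(sprintf("DomainTrack: %d interval(s)\n", nrow(object@intervals)))
  if (nrow(object@intervals) > 0)
    for (i in seq_len(nrow(object@intervals)))
      cat(sprintf("  [%g, %g)\n", object@intervals[i, 1],
                  object@intervals[i, 2]))
})
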
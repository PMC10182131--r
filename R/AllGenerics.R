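#' Confusion-matrix accessors
#'
#' Extract counts and derived rates from a [ConfusionSummary-class].
#' Rates with a zero denominator are \code{NA} (undefined), never 0/0
#' artifacts: PPV = TP/(TP+FP), NPV = TN/(TN+FN),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP).
#'
#' @param x a [ConfusionSummary-class].
#' @return a single numeric value (counts as integers, rates as fractions in
#'   [0, 1] or \code{NA}).
#' @name confusion-accessors
#' @examples
#' cs <- evaluateRule(
#'   data.frame(classification = c("P", "P", "B"),
#'              ddg_fold = c(2.5, 0.2, 0.1), cadd = NA_real_),
#'   thresholdRule(1.8))
#' ppv(cs); specificity(cs)
NULL

#' @rdname confusion-accessors
#' @export
setGeneric("ppv", function(x) standardGeneric("ppv"))
#' @rdname confusion-accessors
#' @export
setGeneric("npv", function(x) standardGeneric("npv"))
#' @rdname confusion-accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname confusion-accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname confusion-accessors
#' @export
setGeneric("truePositives", function(x) standardGeneric("truePositives"))
#' @rdname confusion-accessors
#' @export
setGeneric("falsePositives", function(x) standardGeneric("falsePositives"))
#' @rdname confusion-accessors
#' @export
setGeneric("trueNegatives", function(x) standardGeneric("trueNegatives"))
#' @rdname confusion-accessors
#' @export
setGeneric("falseNegatives", function(x) standardGeneric("falseNegatives"))

#' Structure model accessors
#'
#' @param x a [ProteinModel-class].
#' @return \code{nAtoms}/\code{nResidues}: integer counts;
#'   \code{atomTable}: the atom data.frame; \code{residueConfidence}: named
#'   numeric vector of per-residue confidence scores in [0, 100].
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname model-accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))
#' @rdname model-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname model-accessors
#' @export
setGeneric("residueConfidence",
           function(x) standardGeneric("residueConfidence"))
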
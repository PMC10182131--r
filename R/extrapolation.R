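#' Fraction of known pathogenic variants explained by misfolding
#'
#' Applies a threshold rule to the variants of the stated pathogenic classes
#' and returns the fraction passing — the share of known pathogenic variation
#' attributable to predicted protein destabilization. On the published
#' cohort, 793 of the 6328 P variants (12.5%) exceed both the ddG_Fold and
#' CADD thresholds. The result does not depend on what other classes are
#' present in the table.
#'
#' @inheritParams evaluateRule
#' @param rule a [ThresholdRule-class].
#' @param pathogenicClasses classification labels treated as pathogenic
#'   (default \code{"P"}).
#' @return fraction in [0, 1].
#' @export
misfoldingFraction <- function(variants, rule, pathogenicClasses = "P") {
  .checkVariants(variants)
  sel <- variants$classification %in% pathogenicClasses
  if (!any(sel)) stop("no variants in the pathogenic class set")
  path <- variants[sel, , drop = FALSE]
  sum(rulePass(path, rule)) / nrow(path)
}

#' Extrapolate pathogenic VUSs unrelated to misfolding
#'
#' If the \code{nPrioritized} VUSs flagged as misfolding-pathogenic represent
#' a fraction \code{fraction} of all pathogenic VUSs yet to be found (the
#' fraction observed among already-classified pathogenic variants), the
#' implied total is \code{nPrioritized / fraction} and the remainder —
#' pathogenic for reasons other than misfolding — is
#' \code{round(nPrioritized * (1 - fraction) / fraction)}. With the published
#' inputs (3456 prioritized, fraction 0.125) this is 24,192. Prefer the exact
#' observed fraction from [misfoldingFraction()] for new analyses; pass the
#' rounded printed fraction only to reproduce published arithmetic.
#'
#' @param nPrioritized count of misfolding-prioritized VUSs, >= 0.
#' @param fraction misfolding fraction in (0, 1].
#' @return estimated count (rounded to the nearest integer).
#' @examples
#' estimateRemainingUnrelated(3456, 0.125)   # 24192
#' @export
estimateRemainingUnrelated <- function(nPrioritized, fraction) {
  if (is.na(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (is.na(nPrioritized) || nPrioritized < 0)
    stop("nPrioritized must be >= 0")
  round(nPrioritized * (1 - fraction) / fraction)
}

#' Complement of a passing count, with percentage
#'
#' The variants of a class that do NOT pass a rule, as a count and a percent
#' of the class total (one decimal, half away from zero) — e.g. the 5535 of
#' 6328 pathogenic variants (87.5%) not explained by misfolding.
#'
#' @param total class size.
#' @param passing number passing the rule, \code{<= total}.
#' @return named numeric vector \code{c(count, percent)}.
#' @examples
#' complementCount(6328, 793)   # 5535, 87.5
#' @export
complementCount <- function(total, passing) {
  if (is.na(total) || is.na(passing) || passing > total || passing < 0 ||
      total <= 0)
    stop("need 0 <= passing <= total with total > 0")
  cnt <- total - passing
  c(count = cnt, percent = .round1(100 * cnt / total))
}
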
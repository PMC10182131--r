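#' Equilibrium consequence of a folding free energy difference
#'
#' For a two-state folding equilibrium the ratio of folded to unfolded protein
#' is K = exp(-dG/RT). A variant shifting the folding free energy by
#' \code{ddg} therefore multiplies this ratio by exp(-ddg/RT).
#' \code{foldRatioChange()} returns that multiplicative factor: values below 1
#' are destabilizing (the folded:unfolded ratio shrinks). At standard
#' conditions a ddG_Fold of 1.8 kcal/mol corresponds to a roughly 20-fold
#' decrease of the folded:unfolded ratio, the rationale for the 1.8 kcal/mol
#' prioritization threshold.
#'
#' @param ddg folding free energy difference in kcal/mol (positive =
#'   destabilizing); vectorized.
#' @param params a [ThermoParams-class] (default: R = 1.987e-3 kcal/(mol K),
#'   T = 298.15 K).
#' @return unitless multiplicative change in the folded:unfolded ratio.
#' @examples
#' foldRatioChange(0)            # 1: no change
#' 1 / foldRatioChange(1.8)      # ~20.8-fold decrease
#' foldRatioChange(-1.8)         # ~20.8-fold increase
#' @export
foldRatioChange <- function(ddg, params = thermoParams()) {
  stopifnot(is(params, "ThermoParams"))
  if (any(!is.finite(ddg))) stop("ddg must be finite")
  exp(-ddg / (params@gasConstant * params@temperature))
}

#' ddG_Fold producing a given fold-decrease of the folded:unfolded ratio
#'
#' Inverse of [foldRatioChange()]: the free energy difference RT*ln(k) that
#' shrinks the folded:unfolded equilibrium ratio by a factor \code{k}.
#' \code{ddgForFoldDecrease(20)} is about 1.775 kcal/mol at 298.15 K, rounding
#' to the 1.8 kcal/mol threshold.
#'
#' @param k unitless fold-decrease, > 0; vectorized.
#' @inheritParams foldRatioChange
#' @return ddG in kcal/mol.
#' @examples
#' ddgForFoldDecrease(20)   # ~1.8 kcal/mol
#' ddgForFoldDecrease(1)    # 0
#' @export
ddgForFoldDecrease <- function(k, params = thermoParams()) {
  stopifnot(is(params, "ThermoParams"))
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0")
  params@gasConstant * params@temperature * log(k)
}

#' Folded fraction from the folded:unfolded ratio
#'
#' Converts an equilibrium ratio r = [folded]/[unfolded] into the fraction of
#' protein in the folded state, r/(1+r).
#'
#' @param ratio folded:unfolded ratio, >= 0; vectorized.
#' @return fraction in [0, 1].
#' @examples
#' foldedFraction(1)    # 0.5
#' foldedFraction(19)   # 0.95
#' @export
foldedFraction <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) stop("ratio must be >= 0")
  ratio / (1 + ratio)
}
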
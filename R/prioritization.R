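# Round half away from zero (the convention of the published tables);
# base round() rounds half to even.
.round1 <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Prioritize variants of uncertain significance by the joint rule
#'
#' Applies a joint (ddG_Fold, CADD) rule to the VUS rows of a variant table.
#' VUSs strictly exceeding both cutoffs are returned in input order with
#' \code{passes_ddg}/\code{passes_cadd} flags, a \code{proposed_class} of
#' \code{"LP"} (likely pathogenic due to predicted misfolding), and a
#' human-readable \code{rationale} recording both scores against both
#' cutoffs. Classified rows (B/LB/LP/P) are never touched.
#'
#' @inheritParams evaluateRule
#' @param rule a [ThresholdRule-class] with both cutoffs present.
#' @return data.frame of passing VUS rows with the added columns.
#' @examples
#' v <- data.frame(classification = c("VUS", "VUS", "P"),
#'                 ddg_fold = c(2.0, 2.0, 3.0), cadd = c(30, 20, 30))
#' prioritizeVariants(v, thresholdRule(1.8, 25.7))
#' @export
prioritizeVariants <- function(variants, rule) {
  .checkVariants(variants)
  stopifnot(is(rule, "ThresholdRule"))
  if (is.na(rule@ddgCutoff))
    stop("prioritization requires a ddG_Fold cutoff")
  hasCadd <- !is.na(rule@caddCutoff)
  vus <- variants[variants$classification == "VUS", , drop = FALSE]
  dPass <- rulePass(vus, thresholdRule(rule@ddgCutoff,
                                       direction = rule@direction))
  cPass <- if (hasCadd)
    rulePass(vus, thresholdRule(caddCutoff = rule@caddCutoff))
  else rep(TRUE, nrow(vus))
  out <- vus[dPass & cPass, , drop = FALSE]
  n <- nrow(out)
  out$passes_ddg <- rep(TRUE, n)
  out$passes_cadd <- rep(if (hasCadd) TRUE else NA, n)
  out$proposed_class <- rep("LP", n)
  cmp <- if (rule@direction == "destabilizing") ">" else "< -"
  out$rationale <- sprintf("ddG_Fold %.3f %s %.3g kcal/mol",
                           out$ddg_fold, cmp, rule@ddgCutoff)
  if (hasCadd)
    out$rationale <- sprintf("%s and CADD %.2f > %.3g", out$rationale,
                             out$cadd, rule@caddCutoff)
  rownames(out) <- NULL
  out
}

#' Gene-level summaries of prioritized variants
#'
#' Aggregates prioritized VUSs per gene: count, protein length, variant
#' density per 1000 amino acids, and mean ddG_Fold / CADD over the
#' prioritized rows. Density and means are reported to one decimal (half
#' away from zero). The default \code{minDensity = 30} reproduces the
#' published table's inclusion rule (genes with >= 30 prioritized VUSs per
#' 1000 aa); set it to 0 to keep every gene.
#'
#' @param prioritized output of [prioritizeVariants()].
#' @param geneLengths named numeric vector or data.frame (\code{gene},
#'   \code{length}) giving one protein length per gene.
#' @param minDensity minimum density (per 1000 aa) for inclusion; default 30.
#' @return data.frame with columns \code{gene}, \code{protein_length},
#'   \code{n_prioritized}, \code{density}, \code{mean_ddg}, \code{mean_cadd},
#'   sorted by gene.
#' @examples
#' pri <- data.frame(gene = rep("SLC19A2", 35),
#'                   classification = "VUS",
#'                   ddg_fold = rep(3.5, 35), cadd = rep(28.1, 35))
#' geneSummaries(pri, c(SLC19A2 = 497))   # density 70.4
#' @export
geneSummaries <- function(prioritized, geneLengths, minDensity = 30) {
  if (is.data.frame(geneLengths))
    geneLengths <- setNames(geneLengths$length, geneLengths$gene)
  genes <- unique(prioritized$gene)
  miss <- setdiff(genes, names(geneLengths))
  if (length(miss))
    stop("no protein length for gene(s): ", paste(miss, collapse = ", "))
  rows <- lapply(genes, function(g) {
    rowsG <- prioritized[prioritized$gene == g, , drop = FALSE]
    len <- geneLengths[[g]]
    data.frame(gene = g, protein_length = len,
               n_prioritized = nrow(rowsG),
               density = .round1(1000 * nrow(rowsG) / len),
               mean_ddg = .round1(mean(rowsG$ddg_fold)),
               mean_cadd = .round1(mean(rowsG$cadd)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(), protein_length = numeric(),
                      n_prioritized = integer(), density = numeric(),
                      mean_ddg = numeric(), mean_cadd = numeric()))
  out <- out[out$density >= minDensity, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify variants by a feature and model-confidence bin
#'
#' Builds the confidence-stratified contingency tables of the analysis: rows
#' are either the 5-level classification or the domain flag, columns the four
#' model-confidence bins (<50, 50-70, 70-90, >90). Cell percentages are of
#' the grand total of rows with complete features, to one decimal; rows with
#' a missing feature are tallied separately and excluded from percentages.
#'
#' @inheritParams evaluateRule
#' @param rowKey \code{"classification"} or \code{"in_domain"}.
#' @return list with \code{counts} (matrix with margin totals), \code{pct}
#'   (percent of grand total, one decimal), and \code{n_missing}.
#' @examples
#' v <- generateVariantTable(defaultCohortConfig(), seed = 1)
#' s <- stratifyVariants(v, "classification")
#' s$counts["VUS", "Total"]
#' @export
stratifyVariants <- function(variants,
                             rowKey = c("classification", "in_domain")) {
  rowKey <- match.arg(rowKey)
  if (!rowKey %in% names(variants) || !"confidence" %in% names(variants))
    stop("variants must carry '", rowKey, "' and 'confidence' columns")
  keyVals <- variants[[rowKey]]
  conf <- variants$confidence
  ok <- !is.na(keyVals) & !is.na(conf)
  nMissing <- sum(!ok)
  keyVals <- keyVals[ok]; conf <- conf[ok]
  bins <- c("<50", "50-70", "70-90", ">90")
  rowLv <- if (rowKey == "classification") .CLASS_LEVELS
           else c("TRUE", "FALSE")
  tab <- table(factor(as.character(keyVals), levels = rowLv),
               factor(binConfidence(conf), levels = bins))
  counts <- as.matrix(tab)
  counts <- rbind(counts, Total = colSums(counts))
  counts <- cbind(counts, Total = rowSums(counts))
  storage.mode(counts) <- "integer"
  total <- sum(ok)
  pct <- if (total > 0) .round1(100 * counts / total) else counts * NA_real_
  list(counts = counts, pct = pct, n_missing = nMissing)
}

#' Number of distinct genes carrying prioritized variants
#'
#' @param prioritized output of [prioritizeVariants()].
#' @return integer count of distinct gene symbols.
#' @export
countAffectedGenes <- function(prioritized) {
  if (nrow(prioritized) == 0L) return(0L)
  length(unique(prioritized$gene))
}
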
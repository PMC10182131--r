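#' Pipeline configuration
#'
#' Collects every tunable of [runPipeline()] into one validated list:
#' threshold cutoffs and direction, the classification sets used as
#' calibration positives/negatives, the MAF reclassification cutoff, an
#' optional target PPV for the CADD cutoff search, thermodynamic parameters,
#' the seed, and input/output locations.
#'
#' @param ddgCutoff ddG_Fold cutoff in kcal/mol (default 1.8, the cutoff
#'   corresponding to a ~20-fold folded:unfolded ratio decrease).
#' @param caddCutoff CADD cutoff (default 25.7); \code{NA} to drop the CADD
#'   condition or to have it set by the \code{targetPpv} search.
#' @param direction rule direction, \code{"destabilizing"} or
#'   \code{"overstabilizing"}.
#' @param positiveClasses,negativeClasses calibration class sets (defaults
#'   \code{"P"} and \code{"B"}).
#' @param mafCutoff MAF above which VUSs are relabeled LB (default 0.005).
#' @param targetPpv when not \code{NA} and \code{caddCutoff} is \code{NA},
#'   the CADD cutoff is searched with [findCaddCutoff()] to reach this PPV.
#' @param thermo a [ThermoParams-class].
#' @param seed integer seed for simulation.
#' @param cohort a [CohortConfig-class] used when simulating (default
#'   [defaultCohortConfig()]).
#' @param inputTable path to a variant TSV; \code{NULL} (default) simulates
#'   a cohort from \code{cohort} instead.
#' @param geneLengths optional named vector of protein lengths; defaults to
#'   the cohort's gene catalog.
#' @param outDir optional directory for TSV/JSON outputs.
#' @return a named list of settings (class \code{"pipelineConfig"}).
#' @export
pipelineConfig <- function(ddgCutoff = 1.8, caddCutoff = 25.7,
                           direction = c("destabilizing", "overstabilizing"),
                           positiveClasses = "P", negativeClasses = "B",
                           mafCutoff = 0.005, targetPpv = NA_real_,
                           thermo = thermoParams(), seed = 1,
                           cohort = defaultCohortConfig(),
                           inputTable = NULL, geneLengths = NULL,
                           outDir = NULL) {
  direction <- match.arg(direction)
  if (!is.finite(ddgCutoff)) stop("ddgCutoff must be finite")
  if (!is.na(caddCutoff) && !is.finite(caddCutoff))
    stop("caddCutoff must be finite or NA")
  if (!is.na(targetPpv) && !(targetPpv > 0 && targetPpv <= 1))
    stop("targetPpv must be in (0, 1]")
  stopifnot(is(thermo, "ThermoParams"), is(cohort, "CohortConfig"))
  if (is.null(geneLengths))
    geneLengths <- setNames(cohort@geneCatalog$length,
                            cohort@geneCatalog$gene)
  structure(list(
    ddgCutoff = ddgCutoff, caddCutoff = caddCutoff, direction = direction,
    positiveClasses = positiveClasses, negativeClasses = negativeClasses,
    mafCutoff = mafCutoff, targetPpv = targetPpv, thermo = thermo,
    seed = seed, cohort = cohort, inputTable = inputTable,
    geneLengths = geneLengths, outDir = outDir
  ), class = "pipelineConfig")
}

.confusionAsList <- function(cs) {
  list(tp = truePositives(cs), fp = falsePositives(cs),
       tn = trueNegatives(cs), fn = falseNegatives(cs),
       ppv = ppv(cs), npv = npv(cs),
       sensitivity = sensitivity(cs), specificity = specificity(cs))
}

.stageLog <- function(stage, nIn, nOut, verbose) {
  if (verbose)
    message(sprintf("[%s] %d -> %d rows", stage, nIn, nOut))
}

#' Run the full prioritization pipeline
#'
#' Orchestrates the analysis end to end: acquire a variant table (simulated
#' from the cohort configuration, or read from TSV), reclassify common VUSs
#' by MAF, calibrate the threshold rule on classified variants (confusion
#' matrix for the stability-only rule, then either the configured CADD
#' cutoff or a search for the cutoff reaching the target PPV), prioritize
#' the VUSs passing the joint rule, summarize per gene and per
#' confidence stratum, and extrapolate the pathogenic burden unrelated to
#' misfolding. Deterministic given the seed; each stage logs its row
#' attrition.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log one line per stage (default TRUE).
#' @return a summary list: total/class counts, thresholds (including the
#'   equilibrium-ratio change implied by the ddG cutoff), MAF
#'   reclassifications, both confusion summaries, prioritized count,
#'   affected genes, gene summaries, stratification tables and the
#'   extrapolation. When \code{outDir} is set, also writes
#'   \code{prioritized.tsv}, \code{gene_summaries.tsv},
#'   \code{stratification_*.tsv} and \code{summary.json} there.
#' @examples
#' \donttest{
#' res <- runPipeline(pipelineConfig(seed = 1), verbose = FALSE)
#' res$n_total        # 128167
#' res$n_prioritized
#' }
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  variants <- withStage("acquire", {
    if (is.null(config$inputTable))
      generateVariantTable(config$cohort, seed = config$seed)
    else readVariantTable(config$inputTable)
  })
  .stageLog("acquire", 0L, nrow(variants), verbose)

  n0 <- nrow(variants)
  variants <- withStage("maf_filter", mafFilter(variants, config$mafCutoff))
  nReclass <- sum(variants$maf_reclassified)
  .stageLog("maf_filter", n0, nrow(variants), verbose)

  ddgRule <- thresholdRule(config$ddgCutoff, direction = config$direction)
  csDdg <- withStage("calibrate",
    evaluateRule(variants, ddgRule, config$positiveClasses,
                 config$negativeClasses))
  caddCutoff <- config$caddCutoff
  caddSearched <- FALSE
  if (is.na(caddCutoff) && !is.na(config$targetPpv)) {
    caddCutoff <- withStage("calibrate",
      findCaddCutoff(variants, config$ddgCutoff, config$targetPpv,
                     config$positiveClasses, config$negativeClasses))
    caddSearched <- TRUE
  }
  jointRule <- thresholdRule(config$ddgCutoff,
                             if (is.na(caddCutoff)) NA_real_ else caddCutoff,
                             direction = config$direction)
  csJoint <- withStage("calibrate",
    evaluateRule(variants, jointRule, config$positiveClasses,
                 config$negativeClasses))
  .stageLog("calibrate", nrow(variants), nrow(variants), verbose)

  prioritized <- withStage("prioritize",
                           prioritizeVariants(variants, jointRule))
  .stageLog("prioritize", sum(variants$classification == "VUS"),
            nrow(prioritized), verbose)

  geneSum <- withStage("gene_summaries", {
    covered <- unique(prioritized$gene) %in% names(config$geneLengths)
    if (all(covered)) geneSummaries(prioritized, config$geneLengths)
    else NULL  # lengths unavailable for some genes; summaries skipped
  })

  stratClass <- withStage("stratify",
                          stratifyVariants(variants, "classification"))
  stratDomain <- if ("in_domain" %in% names(variants))
    withStage("stratify", stratifyVariants(variants, "in_domain"))
  else NULL

  extra <- withStage("extrapolate", {
    frac <- misfoldingFraction(variants, jointRule, config$positiveClasses)
    nPath <- sum(variants$classification %in% config$positiveClasses)
    comp <- complementCount(nPath, round(frac * nPath))
    list(misfolding_fraction = frac,
         misfolding_percent = .round1(100 * frac),
         pathogenic_total = nPath,
         pathogenic_unrelated = unname(comp["count"]),
         pathogenic_unrelated_percent = unname(comp["percent"]),
         estimate_remaining_unrelated =
           if (frac > 0) estimateRemainingUnrelated(nrow(prioritized), frac)
           else NA_real_)
  })
  if (verbose)
    message(sprintf(
      "[extrapolate] misfolding fraction %.3f; %d VUS prioritized; est. %s unrelated",
      extra$misfolding_fraction, nrow(prioritized),
      format(extra$estimate_remaining_unrelated, big.mark = ",")))

  summary <- list(
    n_total = nrow(variants),
    n_by_class = as.list(table(variants$classification)),
    thresholds = list(
      ddg_cutoff = config$ddgCutoff, cadd_cutoff = caddCutoff,
      direction = config$direction, cadd_cutoff_searched = caddSearched,
      fold_ratio_change_at_cutoff =
        foldRatioChange(config$ddgCutoff, config$thermo)),
    n_maf_reclassified = nReclass,
    confusion_ddg_only = .confusionAsList(csDdg),
    confusion_joint = .confusionAsList(csJoint),
    n_prioritized = nrow(prioritized),
    n_affected_genes = countAffectedGenes(prioritized),
    extrapolation = extra
  )

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeVariantTable(prioritized,
                      file.path(config$outDir, "prioritized.tsv"))
    if (!is.null(geneSum))
      utils::write.table(geneSum,
                         file.path(config$outDir, "gene_summaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         eol = "\n")
    writeStrat <- function(s, path) {
      df <- data.frame(key = rownames(s$counts),
                       as.data.frame.matrix(s$counts),
                       check.names = FALSE)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n")
    }
    writeStrat(stratClass,
               file.path(config$outDir, "stratification_classification.tsv"))
    if (!is.null(stratDomain))
      writeStrat(stratDomain,
                 file.path(config$outDir, "stratification_domain.tsv"))
    jsonlite::write_json(summary,
                         file.path(config$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }

  c(summary, list(prioritized = prioritized, gene_summaries = geneSum,
                  stratification_classification = stratClass,
                  stratification_domain = stratDomain))
}
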
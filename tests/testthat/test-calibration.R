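test_that("rule evaluation handles separation, degeneracy and disjointness", {
  v <- toyVariants(c("P", "P", "B", "B"), ddg = c(2.5, 2.1, 0.3, -0.2))
  cs <- evaluateRule(v, thresholdRule(1.8))
  expect_identical(ppv(cs), 1)
  expect_identical(specificity(cs), 1)
  expect_identical(sensitivity(cs), 1)
  # nothing passes: PPV undefined, specificity perfect
  cs2 <- evaluateRule(v, thresholdRule(10))
  expect_true(is.na(ppv(cs2)))
  expect_identical(specificity(cs2), 1)
  # variants outside both class sets are ignored
  v3 <- rbind(v, toyVariants("VUS", 5))
  expect_identical(.confusionVec(evaluateRule(v3, thresholdRule(1.8))),
                   .confusionVec(cs))
  expect_error(evaluateRule(v, thresholdRule(1.8),
                            positiveClasses = c("P", "B")), "disjoint")
})

test_that("confusion counts conserve class totals and match a brute-force oracle", {
  set.seed(2024)
  for (rep in 1:5) {
    v <- toyVariants(sample(c("B", "LB", "LP", "P", "VUS"), 100, TRUE),
                     ddg = round(rnorm(100, 0.5, 1.2), 2),
                     cadd = round(runif(100, 5, 40), 1))
    ddgCut <- runif(1, 0, 2)
    caddCut <- runif(1, 10, 35)
    cs <- evaluateRule(v, thresholdRule(ddgCut, caddCut))
    o <- confusionOracle(v, ddgCut, caddCut)
    expect_identical(.confusionVec(cs), unname(o))
    nPos <- sum(v$classification == "P")
    nNeg <- sum(v$classification == "B")
    expect_identical(truePositives(cs) + falseNegatives(cs), nPos)
    expect_identical(falsePositives(cs) + trueNegatives(cs), nNeg)
    # pooled class sets against the oracle too
    cs2 <- evaluateRule(v, thresholdRule(ddgCut),
                        positiveClasses = c("P", "LP"),
                        negativeClasses = c("B", "LB"))
    o2 <- confusionOracle(v, ddgCut, NA, positives = c("P", "LP"),
                          negatives = c("B", "LB"))
    expect_identical(.confusionVec(cs2), unname(o2))
  }
})

test_that("overstabilizing direction selects the opposite tail", {
  v <- toyVariants(c("P", "P", "B"), ddg = c(-2.5, 2.5, -0.1))
  cs <- evaluateRule(v, thresholdRule(1.8, direction = "overstabilizing"))
  expect_identical(truePositives(cs), 1L)   # only ddg = -2.5 passes
  expect_identical(falseNegatives(cs), 1L)
  expect_identical(falsePositives(cs), 0L)
})

test_that("raising a cutoff never increases false positives", {
  set.seed(9)
  v <- toyVariants(sample(c("B", "P"), 200, TRUE), ddg = rnorm(200, 0.5, 1),
                   cadd = rnorm(200, 20, 5))
  fps <- vapply(seq(-1, 3, by = 0.5), function(cut)
    falsePositives(evaluateRule(v, thresholdRule(cut, 20))), integer(1))
  expect_true(all(diff(fps) <= 0))
  fps2 <- vapply(seq(10, 30, by = 2), function(cut)
    falsePositives(evaluateRule(v, thresholdRule(1.0, cut))), integer(1))
  expect_true(all(diff(fps2) <= 0))
})

test_that("CADD cutoff search returns the minimal candidate reaching the target", {
  v <- toyVariants(c("P", "P", "P", "B", "B"),
                   ddg = c(2.0, 2.5, 1.0, 2.0, 0.5),
                   cadd = c(30, 20, 40, 26, 35))
  expect_identical(findCaddCutoff(v, 1.8, 1.0), 26)
  # an easy target is met at the smallest observed candidate
  expect_identical(findCaddCutoff(v, 1.8, 0.5), 20)
  # all passing variants negative: unattainable
  vNeg <- toyVariants(c("B", "B", "P"), ddg = c(2.0, 2.2, 0.1),
                      cadd = c(30, 25, 40))
  expect_true(is.na(findCaddCutoff(vNeg, 1.8, 0.9)))
  # nothing passes the ddG cutoff: failure marker
  expect_true(is.na(findCaddCutoff(v, 10, 0.9)))
  expect_error(findCaddCutoff(v, 1.8, 0), "\\(0, 1\\]")
})

test_that("cutoff search minimality holds by exhaustive enumeration", {
  set.seed(55)
  for (rep in 1:5) {
    v <- toyVariants(sample(c("B", "P"), 40, TRUE),
                     ddg = round(rnorm(40, 1.2, 1), 2),
                     cadd = round(runif(40, 10, 35), 1))
    target <- runif(1, 0.6, 1)
    got <- findCaddCutoff(v, 1.0, target)
    pool <- v[v$ddg_fold > 1.0, ]
    candidates <- sort(unique(pool$cadd))
    ppvAt <- vapply(candidates, function(c) {
      o <- confusionOracle(v, 1.0, c)
      if (o["tp"] + o["fp"] == 0) NA_real_
      else o[["tp"]] / (o[["tp"]] + o[["fp"]])
    }, numeric(1))
    attain <- candidates[!is.na(ppvAt) & ppvAt >= target]
    if (length(attain) == 0) expect_true(is.na(got))
    else {
      expect_identical(got, min(attain))
      below <- candidates[candidates < got]
      if (length(below))
        expect_true(all(is.na(ppvAt[candidates %in% below]) |
                          ppvAt[candidates %in% below] < target))
    }
  }
})

test_that("threshold sweep is consistent with single evaluations and monotone in PPV", {
  v <- toyVariants(c("P", "P", "P", "B", "B"),
                   ddg = c(2.0, 2.5, 1.0, 2.0, 0.5),
                   cadd = c(30, 20, 40, 26, 35))
  sw <- sweepThresholds(v, 1.8, 26)
  cs <- evaluateRule(v, thresholdRule(1.8, 26))
  expect_identical(sw$tp, truePositives(cs))
  expect_identical(sw$ppv, ppv(cs))
  # PPV non-decreasing in the CADD cutoff on this toy set
  sw2 <- sweepThresholds(v, 1.8, c(20, 26, 30))
  p <- sw2$ppv[!is.na(sw2$ppv)]
  expect_true(all(diff(p) >= 0))
  # deterministic ddG-major ordering
  sw3 <- sweepThresholds(v, c(1.0, 1.8), c(20, 26))
  expect_identical(sw3$ddg_cutoff, c(1.0, 1.0, 1.8, 1.8))
  expect_identical(sw3$cadd_cutoff, c(20, 26, 20, 26))
  # empty variant table: every PPV undefined
  sw4 <- sweepThresholds(v[0, ], c(1, 2), c(20, 30))
  expect_true(all(is.na(sw4$ppv)))
  expect_error(sweepThresholds(v, numeric(), 20), "non-empty")
})

test_that("MAF filter relabels only common VUSs and records provenance", {
  v <- toyVariants(c("VUS", "VUS", "P", "VUS"), ddg = 1:4, cadd = 20,
                   maf = c(0.1, NA, 0.1, 0.001))
  out <- mafFilter(v, 0.005)
  expect_identical(out$classification, c("LB", "VUS", "P", "VUS"))
  expect_identical(out$maf_reclassified, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(mafFilter(v, 1.5), "\\[0, 1\\]")
})
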
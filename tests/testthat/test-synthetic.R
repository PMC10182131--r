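test_that("default configuration reproduces the published cohort structure", {
  cfg <- defaultCohortConfig()
  profs <- cohortProfiles(cfg)
  counts <- vapply(profs, function(p) p@count, numeric(1))
  names(counts) <- vapply(profs, function(p) p@label, character(1))
  expect_identical(sum(counts), 128167)
  expect_identical(counts[["VUS"]], 89766)
  byLab <- setNames(profs, names(counts))
  expect_equal(byLab$P@ddgMean, 0.80)
  expect_equal(byLab$B@ddgMean, 0.13)
  # SDs are solved from the published tail constraints
  expect_equal(pnorm(1.8, 0.80, byLab$P@ddgSd, lower.tail = FALSE),
               1067 / 6328, tolerance = 1e-3)
  expect_equal(pnorm(1.8, 0.13, byLab$B@ddgSd, lower.tail = FALSE),
               32 / 1725, tolerance = 1e-4)
  expect_equal(byLab$P@ddgSd, 1.042, tolerance = 1e-3)
  expect_equal(byLab$B@ddgSd, 0.801, tolerance = 1e-3)
  # LB/LP reuse B/P score distributions
  expect_equal(byLab$LB@ddgMean, byLab$B@ddgMean)
  expect_equal(byLab$LP@ddgSd, byLab$P@ddgSd)
  for (p in profs) expect_equal(sum(p@confBinProbs), 1, tolerance = 1e-12)
})

test_that("profile and config validity catch bad parameters", {
  expect_error(classProfile("P", -1, 0.8, 1, 26, 3, 0.4, rep(0.25, 4)),
               "non-negative")
  expect_error(classProfile("P", 10, 0.8, 0, 26, 3, 0.4, rep(0.25, 4)),
               "ddgSd")
  expect_error(classProfile("P", 10, 0.8, 1, 26, 3, 1.0, rep(0.25, 4)),
               "rho")
  expect_error(classProfile("P", 10, 0.8, 1, 26, 3, 0.4, c(0.5, 0.5, 0.1, 0)),
               "summing to 1")
  expect_error(defaultCohortConfig(vusPathogenicFraction = 1.2))
})

test_that("generated tables are deterministic and respect class counts", {
  cfg <- smallCohortConfig(nB = 300, nP = 300, nVUS = 400)
  v1 <- generateVariantTable(cfg, seed = 7)
  v2 <- generateVariantTable(cfg, seed = 7)
  expect_identical(v1, v2)
  expect_identical(as.vector(table(v1$classification)[c("B", "P", "VUS")]),
                   c(300L, 300L, 400L))
  v3 <- generateVariantTable(cfg, seed = 8)
  expect_false(identical(v1$ddg_fold, v3$ddg_fold))
  # zero counts everywhere give an empty, well-formed table
  empty <- smallCohortConfig(nB = 0, nP = 0, nVUS = 0)
  e <- generateVariantTable(empty, seed = 1)
  expect_identical(nrow(e), 0L)
  expect_true(all(c("gene", "classification", "ddg_fold", "cadd") %in%
                    names(e)))
})

test_that("per-class RNG streams are independent of the other classes", {
  full <- smallCohortConfig(nB = 500, nP = 500, nVUS = 500)
  noVus <- smallCohortConfig(nB = 500, nP = 500, nVUS = 0)
  vFull <- generateVariantTable(full, seed = 11)
  vNoVus <- generateVariantTable(noVus, seed = 11)
  for (cl in c("B", "P"))
    expect_identical(vFull$ddg_fold[vFull$classification == cl],
                     vNoVus$ddg_fold[vNoVus$classification == cl])
})

test_that("class-conditional score distributions recover profile parameters", {
  cfg <- defaultCohortConfig()
  v <- generateVariantTable(cfg, seed = 3)
  byLab <- setNames(cohortProfiles(cfg),
                    vapply(cohortProfiles(cfg), function(p) p@label,
                           character(1)))
  for (cl in c("B", "LB", "LP", "P")) {
    p <- byLab[[cl]]
    rows <- v[v$classification == cl, ]
    n <- nrow(rows)
    # sample means within 4 standard errors of the profile parameters
    expect_lt(abs(mean(rows$ddg_fold) - p@ddgMean), 4 * p@ddgSd / sqrt(n))
    expect_lt(abs(mean(rows$cadd) - p@caddMean), 4 * p@caddSd / sqrt(n))
    expect_lt(abs(sd(rows$ddg_fold) - p@ddgSd), 4 * p@ddgSd / sqrt(n))
    # positive score correlation close to rho at large n
    r <- cor(rows$ddg_fold, rows$cadd)
    expect_gt(r, 0)
    if (n >= 10000) expect_lt(abs(r - p@rho), 0.05)
  }
  # confidence-bin proportions match the multinomial probabilities
  for (cl in c("LB", "VUS")) {
    p <- byLab[[cl]]
    rows <- v[v$classification == cl, ]
    emp <- as.vector(table(factor(binConfidence(rows$confidence),
                                  levels = c("<50", "50-70", "70-90",
                                             ">90")))) / nrow(rows)
    se <- sqrt(p@confBinProbs * (1 - p@confBinProbs) / nrow(rows))
    expect_true(all(abs(emp - p@confBinProbs) < 4 * se + 1e-12))
  }
})

test_that("VUS rows follow the latent pathogenic/benign mixture", {
  cfg <- smallCohortConfig(nB = 1, nP = 1, nVUS = 40000, vusFraction = 0.28)
  v <- generateVariantTable(cfg, seed = 5)
  vus <- v[v$classification == "VUS", ]
  mixMean <- 0.28 * 0.80 + 0.72 * 0.13
  expect_equal(mean(vus$ddg_fold), mixMean, tolerance = 0.03)
  # a pure-benign mixture has a much lighter destabilizing tail
  cfg0 <- smallCohortConfig(nB = 1, nP = 1, nVUS = 40000, vusFraction = 0)
  v0 <- generateVariantTable(cfg0, seed = 5)
  expect_gt(mean(vus$ddg_fold > 1.8),
            2 * mean(v0$ddg_fold[v0$classification == "VUS"] > 1.8))
})

test_that("toy helix structures have ideal geometry and span-driven confidence", {
  m <- generateToyStructure(100, domainSpans = list(c(21, 80)), seed = 1)
  expect_identical(nResidues(m), 100L)
  conf <- residueConfidence(m)
  expect_identical(sum(conf > 90), 60L)
  expect_true(all(conf[21:80] > 90))
  expect_true(all(conf[c(1:20, 81:100)] >= 30 & conf[c(1:20, 81:100)] < 50))
  ca <- atomTable(m)[atomTable(m)$name == "CA", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(abs(d - 3.8) < 0.3))
  # minimal case and argument validation
  expect_identical(nResidues(generateToyStructure(1, seed = 1)), 1L)
  expect_error(generateToyStructure(0), ">= 1")
  expect_error(generateToyStructure(10, list(c(5, 11))), "within")
  # determinism
  expect_identical(generateToyStructure(20, list(c(3, 9)), seed = 4),
                   generateToyStructure(20, list(c(3, 9)), seed = 4))
})
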
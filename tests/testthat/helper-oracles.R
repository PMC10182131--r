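# Shared fixtures and independent oracles for the test suite.

# Build a ProteinModel from bare coordinates (all carbon unless stated).
makeModel <- function(xyz, resno = seq_len(nrow(xyz)), element = "C",
                      confidence = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  element <- rep_len(element, n)
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  at <- data.frame(element = element, radius = unname(radii[element]),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   resno = resno, resid = rep("ALA", n),
                   name = sprintf("C%d", seq_len(n)),
                   stringsAsFactors = FALSE)
  nres <- length(unique(resno))
  if (is.null(confidence)) confidence <- rep(80, nres)
  new("ProteinModel", atoms = at,
      confidence = stats::setNames(confidence, sort(unique(resno))))
}

# Monte-Carlo SASA oracle: random (not quadrature) directions per atom,
# brute-force point-in-sphere burial test. Independent of the package's
# golden-spiral implementation.
mcSasaOracle <- function(model, probe = 1.4, nPoints = 8000) {
  at <- model@atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$radius + probe
  n <- nrow(at)
  area <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(nPoints * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, xyz[i, ], "+")
    buried <- rep(FALSE, nPoints)
    for (j in seq_len(n)[-i])
      buried <- buried | (rowSums(sweep(pts, 2, xyz[j, ])^2) < R[j]^2)
    area[i] <- mean(!buried) * 4 * pi * R[i]^2
  }
  res <- tapply(area, at$resno, sum)
  stats::setNames(as.numeric(res), names(res))
}

# Exhaustive per-variant confusion oracle: one explicit if/else per row.
confusionOracle <- function(variants, ddgCutoff = NA, caddCutoff = NA,
                            positives = "P", negatives = "B",
                            direction = "destabilizing") {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(variants))) {
    cl <- variants$classification[i]
    if (!(cl %in% c(positives, negatives))) next
    pass <- TRUE
    if (!is.na(ddgCutoff)) {
      d <- variants$ddg_fold[i]
      ok <- if (direction == "destabilizing") !is.na(d) && d > ddgCutoff
            else !is.na(d) && d < -ddgCutoff
      pass <- pass && ok
    }
    if (!is.na(caddCutoff)) {
      cd <- variants$cadd[i]
      pass <- pass && !is.na(cd) && cd > caddCutoff
    }
    if (cl %in% positives) { if (pass) tp <- tp + 1L else fn <- fn + 1L }
    else { if (pass) fp <- fp + 1L else tn <- tn + 1L }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

.confusionVec <- function(cs) {
  c(truePositives(cs), falsePositives(cs), trueNegatives(cs),
    falseNegatives(cs))
}

# Minimal classified variant table from parallel score vectors.
toyVariants <- function(classification, ddg, cadd = NA_real_,
                        gene = "GENE1", maf = NA_real_) {
  data.frame(gene = gene,
             protein_change = paste0("p.Ala", seq_along(classification), "Val"),
             classification = classification,
             ddg_fold = ddg, cadd = rep_len(cadd, length(classification)),
             maf = rep_len(maf, length(classification)),
             stringsAsFactors = FALSE)
}

# Small cohort configuration for fast stochastic tests.
smallCohortConfig <- function(nB = 2000, nP = 2000, nVUS = 2000,
                              vusFraction = 0.28) {
  cfg <- defaultCohortConfig(vusPathogenicFraction = vusFraction)
  profs <- lapply(cohortProfiles(cfg), function(p) {
    p@count <- switch(p@label, B = nB, P = nP, VUS = nVUS, 0)
    p
  })
  new("CohortConfig", profiles = profs, vusPathogenicFraction = vusFraction,
      geneCatalog = cfg@geneCatalog)
}
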
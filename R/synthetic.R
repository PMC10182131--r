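# Confidence-bin counts per classification row of the curated database
# (columns: <50, 50-70, 70-90, >90); used as multinomial bin probabilities.
.CONF_BIN_COUNTS <- list(
  B   = c(719, 231, 506, 269),
  LB  = c(15395, 3153, 5973, 3386),
  LP  = c(579, 203, 827, 832),
  P   = c(1201, 470, 2084, 2573),
  VUS = c(25707, 10306, 30106, 23647)
)

# Fraction of variants inside an annotated domain, per confidence bin
# (domain x confidence contingency of the curated database, column-wise).
.DOMAIN_BY_BIN <- c(3371, 5610, 23991, 20028) /
  c(43611, 14393, 39574, 30956)

# Published gene catalog: gene symbol and canonical protein length (aa).
.GENE_CATALOG <- data.frame(
  gene = c("ATP6V1B1", "CDC14A", "CLRN1", "DCAF17", "DIABLO", "ELMOD3",
           "GIPC3", "GJB2", "GJB3", "GRXCR1", "GSDME", "HARS2", "KARS1",
           "LHFPL5", "LOXL3", "MANBA", "MASP1", "MSRB3", "MYO3A", "MYO6",
           "MYO7A", "NARS2", "OTOF", "OTOGL", "PCDH15", "POLR1C", "RDX",
           "SEMA3E", "SLC17A8", "SLC19A2", "SLC22A4", "SLC26A4", "SLC44A4",
           "SLC52A2", "SLC52A3", "TECTA", "TMC1", "TSPEAR", "WFS1"),
  length = c(513, 623, 232, 520, 239, 381, 312, 226, 270, 290, 496, 512,
             625, 219, 753, 879, 728, 185, 1616, 1294, 2215, 477, 1997,
             2344, 1790, 346, 604, 775, 589, 497, 551, 780, 710, 445, 469,
             2155, 760, 601, 890),
  stringsAsFactors = FALSE
)

.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Glu", "Gln", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

# Per-class RNG sub-seed: a fixed function of (seed, class label) so that
# adding or removing a class never perturbs another class's draws.
.classSeed <- function(seed, label) {
  idx <- match(label, .CLASS_LEVELS)
  as.integer((as.numeric(seed) * 1009 + 7919 * idx) %% 2147483647)
}

# Normal SD solved from a single tail constraint P(X > cutoff) = tailProb
# given the mean: sd = (cutoff - mean) / qnorm(1 - tailProb).
.sdFromTail <- function(mean, cutoff, tailProb) {
  (cutoff - mean) / qnorm(1 - tailProb)
}

#' Default synthetic cohort configuration
#'
#' Builds the cohort the calibration analysis assumes: 128,167 missense
#' variants split into B (n = 1725), LB (n = 27,907), LP (n = 2441),
#' P (n = 6328) and VUS (n = 89,766). Scores are class-conditional bivariate
#' normal: the pathogenic class has mean ddG_Fold 0.80 kcal/mol and the benign
#' class 0.13 kcal/mol, with SDs solved from the published tail constraints
#' (1067 of 6328 P variants and about 32 of 1725 B variants above
#' 1.8 kcal/mol, the pair consistent with the published PPV 97.1% and
#' specificity 98.2%), giving sigma_P = 1.042 and sigma_B = 0.801 kcal/mol.
#' CADD marginals default to N(26, 3) for P and N(16, 5) for B with a ddG/CADD
#' correlation of 0.4, chosen so the P-class joint exceedance of
#' \{ddG > 1.8, CADD > 25.7\} is near the published 793/6328. LB and LP reuse
#' the B and P score distributions. Confidence-bin probabilities are the
#' published classification-by-confidence contingency row proportions.
#'
#' VUS scores are a latent two-component mixture of the P- and B-class
#' distributions with pathogenic fraction 0.28, which reproduces a prioritized
#' count near the published 3456 at the default cohort size; the mixture
#' fraction is a modelling device, not an estimate of the true VUS
#' composition.
#'
#' @param vusPathogenicFraction probability that a VUS score pair is drawn
#'   from the pathogenic-class distribution; default 0.28.
#' @param geneCatalog data.frame of columns \code{gene}, \code{length};
#'   defaults to the 39 published genes with high prioritized-variant density.
#' @return a [CohortConfig-class].
#' @examples
#' cfg <- defaultCohortConfig()
#' sum(vapply(cohortProfiles(cfg), function(p) p@count, numeric(1)))  # 128167
#' @export
defaultCohortConfig <- function(vusPathogenicFraction = 0.28,
                                geneCatalog = .GENE_CATALOG) {
  counts <- c(B = 1725, LB = 27907, LP = 2441, P = 6328, VUS = 89766)
  sigP <- .sdFromTail(0.80, 1.8, 1067 / 6328)
  sigB <- .sdFromTail(0.13, 1.8, 32 / 1725)
  pars <- list(  # (ddgMean, ddgSd, caddMean, caddSd, rho)
    B  = c(0.13, sigB, 16, 5, 0.4),
    LB = c(0.13, sigB, 16, 5, 0.4),
    LP = c(0.80, sigP, 26, 3, 0.4),
    P  = c(0.80, sigP, 26, 3, 0.4)
  )
  f <- vusPathogenicFraction
  # VUS marginal parameters are informational (draws use the latent mixture)
  pars$VUS <- c(f * 0.80 + (1 - f) * 0.13,
                sqrt(f * sigP^2 + (1 - f) * sigB^2),
                f * 26 + (1 - f) * 16,
                sqrt(f * 9 + (1 - f) * 25), 0.4)
  profiles <- lapply(.CLASS_LEVELS, function(lab) {
    p <- pars[[lab]]
    cnt <- .CONF_BIN_COUNTS[[lab]]
    classProfile(lab, counts[[lab]], ddgMean = p[1], ddgSd = p[2],
                 caddMean = p[3], caddSd = p[4], rho = p[5],
                 confBinProbs = cnt / sum(cnt))
  })
  new("CohortConfig", profiles = profiles,
      vusPathogenicFraction = vusPathogenicFraction,
      geneCatalog = geneCatalog)
}

#' @return \code{cohortProfiles}: the list of [ClassProfile-class] objects.
#' @rdname defaultCohortConfig
#' @param config a [CohortConfig-class].
#' @export
cohortProfiles <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  config@profiles
}

# Draw n correlated (ddg, cadd) pairs for one profile parameter vector.
.drawScores <- function(n, ddgMean, ddgSd, caddMean, caddSd, rho) {
  if (n == 0L)
    return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("ddg", "cadd"))))
  Sigma <- matrix(c(ddgSd^2, rho * ddgSd * caddSd,
                    rho * ddgSd * caddSd, caddSd^2), 2, 2)
  m <- MASS::mvrnorm(n, mu = c(ddgMean, caddMean), Sigma = Sigma)
  m <- matrix(m, ncol = 2)  # mvrnorm drops to a vector when n = 1
  colnames(m) <- c("ddg", "cadd")
  m
}

.BIN_LOWER <- c(0, 50, 70, 90)
.BIN_UPPER <- c(50, 70, 90, 100)

#' Generate a synthetic variant table
#'
#' Draws one cohort from a [CohortConfig-class]: per class, (ddG_Fold, CADD)
#' pairs from the profile's bivariate normal (VUS rows from the latent
#' P/B mixture), a model-confidence value uniform within a multinomially
#' chosen confidence bin, a domain flag whose probability depends on the
#' confidence bin, a rare minor allele frequency (log-uniform between 1e-8
#' and 1e-4), genes assigned round-robin from the catalog, and residue
#' positions uniform over each protein's length. Each class uses its own RNG
#' stream seeded from (seed, class label), so the output is byte-for-byte
#' deterministic given (config, seed) and adding a class does not perturb the
#' other classes' draws.
#'
#' @param config a [CohortConfig-class].
#' @param seed integer seed.
#' @return data.frame with one row per variant and columns \code{gene},
#'   \code{protein_change}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{classification}, \code{ddg_fold}, \code{cadd}, \code{maf},
#'   \code{confidence}, \code{sasa_pct}, \code{in_domain}
#'   (\code{sasa_pct} is left missing: it is a structure-derived feature,
#'   see [sasaPerResidue()]).
#' @examples
#' cfg <- defaultCohortConfig()
#' v <- generateVariantTable(cfg, seed = 1)
#' table(v$classification)
#' @export
generateVariantTable <- function(config, seed) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  labs <- vapply(config@profiles, function(p) p@label, character(1))
  byLab <- setNames(config@profiles, labs)
  ord <- intersect(.CLASS_LEVELS, labs)
  gc <- config@geneCatalog
  if (nrow(gc) == 0L) stop("geneCatalog is empty")

  one <- function(lab) {
    prof <- byLab[[lab]]
    n <- as.integer(prof@count)
    if (n < 0L) stop("negative class count")
    if (n == 0L) return(NULL)
    set.seed(.classSeed(seed, lab))
    if (lab == "VUS" && config@vusPathogenicFraction > 0) {
      if (!all(c("P", "B") %in% labs))
        stop("VUS mixture requires both P and B profiles")
      latent <- rbinom(n, 1L, config@vusPathogenicFraction)
      scores <- matrix(NA_real_, n, 2)
      for (comp in c("P", "B")) {
        idx <- which(latent == (comp == "P"))
        cp <- byLab[[comp]]
        scores[idx, ] <- .drawScores(length(idx), cp@ddgMean, cp@ddgSd,
                                     cp@caddMean, cp@caddSd, cp@rho)
      }
    } else {
      scores <- .drawScores(n, prof@ddgMean, prof@ddgSd, prof@caddMean,
                            prof@caddSd, prof@rho)
    }
    bin <- sample.int(4L, n, replace = TRUE, prob = prof@confBinProbs)
    conf <- runif(n, .BIN_LOWER[bin], .BIN_UPPER[bin])
    inDom <- rbinom(n, 1L, .DOMAIN_BY_BIN[bin]) == 1L
    maf <- 10^runif(n, -8, -4)
    gi <- ((seq_len(n) - 1L) %% nrow(gc)) + 1L
    len <- gc$length[gi]
    posAA <- 1L + as.integer(floor(runif(n) * len))  # uniform in [1, length]
    refAA <- .AA3[sample.int(20L, n, replace = TRUE)]
    altAA <- .AA3[sample.int(20L, n, replace = TRUE)]
    nt <- c("A", "C", "G", "T")
    ref <- nt[sample.int(4L, n, replace = TRUE)]
    alt <- nt[((match(ref, nt) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
    data.frame(
      gene = gc$gene[gi],
      protein_change = paste0("p.", refAA, posAA, altAA),
      chrom = as.character(((gi - 1L) %% 22L) + 1L),
      pos = 1000000L + 3L * posAA + gi,
      ref = ref, alt = alt,
      classification = lab,
      ddg_fold = scores[, 1], cadd = scores[, 2],
      maf = maf, confidence = conf, sasa_pct = NA_real_,
      in_domain = inDom,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(ord, one))
  if (is.null(out)) {  # every class count was 0
    out <- data.frame(gene = character(), protein_change = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      classification = character(), ddg_fold = numeric(),
                      cadd = numeric(), maf = numeric(),
                      confidence = numeric(), sasa_pct = numeric(),
                      in_domain = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Generate an idealized helical toy structure
#'
#' Builds a poly-alanine alpha-helix (rise 1.5 Angstrom and 100 degrees of
#' turn per residue) with backbone N, CA, C, O and a CB per residue, giving
#' the surface-area and clash operators a geometrically sensible input
#' without any structure prediction. Per-residue confidence is sampled high
#' (in (90, 100]) inside the supplied domain spans and low (in [30, 50))
#' outside, mimicking the confident-domain / disordered-linker contrast of
#' predicted structures.
#'
#' @param length number of residues, >= 1.
#' @param domainSpans two-column matrix or list of c(start, end) pairs,
#'   1-based inclusive residue ranges within [1, length]; may be empty.
#' @param seed integer seed for the confidence draws.
#' @return a [ProteinModel-class].
#' @examples
#' m <- generateToyStructure(30, list(c(5, 20)), seed = 1)
#' nResidues(m)
#' @export
generateToyStructure <- function(length, domainSpans = list(), seed = 1) {
  if (length(length) != 1L || is.na(length) || length < 1)
    stop("length must be >= 1")
  length <- as.integer(length)
  if (is.matrix(domainSpans))
    domainSpans <- lapply(seq_len(nrow(domainSpans)),
                          function(i) domainSpans[i, ])
  for (sp in domainSpans) {
    if (length(sp) != 2L || sp[1] > sp[2] || sp[1] < 1 || sp[2] > length)
      stop("domain spans must be (start <= end) within [1, length]")
  }
  i <- seq_len(length)
  theta <- (i - 1) * 100 * pi / 180
  z <- (i - 1) * 1.5
  helix <- function(r, dTheta, dz, elem, nm) {
    data.frame(element = elem, radius = .VDW_RADII[[elem]],
               x = r * cos(theta + dTheta), y = r * sin(theta + dTheta),
               z = z + dz, resno = i, resid = "ALA", name = nm,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(
    helix(1.60, -28 * pi / 180, -0.90, "N", "N"),
    helix(2.30, 0, 0, "C", "CA"),
    helix(1.70, 28 * pi / 180, 0.80, "C", "C"),
    helix(2.00, 45 * pi / 180, 1.00, "O", "O"),
    helix(3.40, 0, 0.20, "C", "CB")
  )
  atoms <- atoms[order(atoms$resno), ]
  rownames(atoms) <- NULL
  inSpan <- rep(FALSE, length)
  for (sp in domainSpans) inSpan[sp[1]:sp[2]] <- TRUE
  set.seed(.classSeed(seed, "B") + 31L)  # structure stream
  conf <- ifelse(inSpan, runif(length, 90, 100), runif(length, 30, 50))
  new("ProteinModel", atoms = atoms,
      confidence = setNames(conf, as.character(i)))
}
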
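---
title: "Prioritizing uncertain missense variants by predicted protein destabilization"
author: "foldvus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing uncertain missense variants by predicted protein destabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldvus)
```

## The problem

Curated disease-gene databases classify missense variants on a five-level
scale — benign (B), likely benign (LB), likely pathogenic (LP), pathogenic
(P) and variant of uncertain significance (VUS) — and VUSs typically
dominate. A VUS blocks a definitive molecular diagnosis. One mechanistic
route to reclassification is protein stability: a variant with a large
positive folding free energy difference (ΔΔG_Fold, kcal/mol) shifts the
folding equilibrium away from the native state, and misfolding followed by
loss of function or degradation is a plausible pathogenic mechanism. This
package implements the calibration-and-prioritization analysis built on that
idea: choose a ΔΔG_Fold threshold with a thermodynamic interpretation,
calibrate it (and a companion CADD deleteriousness threshold) against
expert-classified variants using confusion-matrix statistics, flag the VUSs
exceeding both cutoffs as likely pathogenic due to misfolding, and
extrapolate how much pathogenic variation the stability axis cannot explain.

## The thermodynamic threshold

For a two-state folder the folded:unfolded ratio is $K = e^{-\Delta
G/RT}$, so a variant shifting the folding free energy by $\Delta\Delta G$
multiplies that ratio by $e^{-\Delta\Delta G/RT}$:

```{r}
1 / foldRatioChange(1.8)     # ~20-fold decrease in folded:unfolded
ddgForFoldDecrease(20)       # the ddG producing exactly a 20-fold decrease
```

A 20-fold depletion of the folded state is an interpretable notion of
"appreciably destabilizing", and $RT\ln 20$ rounds to 1.8 kcal/mol at both
298.15 K and 310.15 K — the default threshold is therefore robust to the
choice of standard versus physiological temperature. We default to 298.15 K
and expose the temperature through `thermoParams()`.

## The synthetic calibration cohort

The original analysis ran on a proprietary expert-curated database joined to
structure-based ΔΔG_Fold predictions and CADD scores. To make every stage of
the pipeline testable without those resources, `defaultCohortConfig()`
defines a synthetic cohort with the statistical structure the calibration
rests on:

* class sizes 1725 (B), 27,907 (LB), 2441 (LP), 6328 (P) and 89,766 (VUS) —
  128,167 variants in total;
* class-conditional (ΔΔG_Fold, CADD) pairs drawn from bivariate normal
  distributions. The pathogenic class has mean ΔΔG_Fold 0.80 kcal/mol and
  the benign class 0.13 kcal/mol. The SDs are not free parameters: they are
  solved from the tail constraints the published confusion metrics imply.
  With 1067 of 6328 P variants above 1.8 kcal/mol,
  $\sigma_P = (1.8-0.80)/\Phi^{-1}(1-1067/6328) = 1.042$; the printed
  PPV/specificity pair (97.1%, 98.2%) is jointly consistent only with
  positives = P, negatives = B and about 32 benign false positives, giving
  $\sigma_B = (1.8-0.13)/\Phi^{-1}(1-32/1725) = 0.801$;
* CADD marginals N(26, 3) for P/LP and N(16, 5) for B/LB with a ΔΔG/CADD
  correlation of 0.4, fixed once by checking (by numerical bivariate-normal
  integration, before any test was written) that the implied P-class joint
  exceedance of {ΔΔG > 1.8, CADD > 25.7} is near the published 793/6328 and
  the joint-rule PPV is near 99%;
* VUS scores drawn from a two-component latent mixture of the P and B
  distributions with pathogenic fraction 0.28. Nothing is published about
  the true composition of VUSs; the mixture is the minimal generative
  assumption, and 0.28 is the value at which the joint rule prioritizes
  about 3456 VUSs at the default cohort size. It is a modelling device, not
  a biological estimate;
* per-residue model-confidence bins (<50, 50–70, 70–90, >90) drawn
  multinomially with the published classification-by-confidence row
  proportions, and a domain flag whose probability per confidence bin
  follows the published domain-by-confidence contingency;
* minor allele frequencies log-uniform on $[10^{-8}, 10^{-4}]$: rare enough
  that the default 0.005 MAF reclassification cutoff never fires (so the
  calibration counts above are undisturbed), while lower cutoffs still
  exercise the filter;
* genes assigned round-robin from a catalog of 39 published gene symbols
  with their canonical protein lengths; residue positions uniform per
  protein; genomic coordinates are placeholders.

Each class draws from its own RNG stream seeded from (seed, class label), so
cohorts are reproducible and removing a class never perturbs the others:

```{r}
cfg <- defaultCohortConfig()
v <- generateVariantTable(cfg, seed = 1)
table(v$classification)
```

What the generator deliberately does **not** emulate: heavy-tailed and
skewed empirical ΔΔG distributions, gene- and domain-dependent score
structure, correlated variants at hotspot positions, measurement error in
the ΔΔG predictor, or realistic genome coordinates. Tests passing on this
cohort therefore validate the *machinery* (thresholding, counting, search,
arithmetic) and the *calibration targets*, not the biological accuracy of
any score on real proteins.

## Calibration and prioritization

`evaluateRule()` computes the confusion matrix of a `thresholdRule()` over
classified variants. Comparisons are strict (`>`), matching the
published rule statements; ties have probability zero for continuous scores.
Destabilization is the default direction; `direction = "overstabilizing"`
(pass iff ΔΔG < −cutoff) supports the analysis of strongly stabilizing
variants, which achieved a markedly lower PPV in the original analysis and
is not part of the default rule.

```{r}
evaluateRule(v, thresholdRule(1.8), positiveClasses = "P",
             negativeClasses = "B")
```

The positives/negatives default to {P} versus {B}: that is the only
assignment jointly consistent with the published TP count, PPV and
specificity. Pooled sets ({P, LP} versus {B, LB}) are a supported
alternative. `findCaddCutoff()` searches the smallest CADD candidate (among
observed CADD values of classified variants passing the ΔΔG cutoff) whose
joint rule reaches a target PPV — the construction that put the published
CADD cutoff at 25.7 for a 99% PPV:

```{r}
prioritized <- prioritizeVariants(v, thresholdRule(1.8, 25.7))
nrow(prioritized)
countAffectedGenes(prioritized)
```

Prioritized VUSs are proposed as **LP** (not P): the output carries the
rationale string and the rule, and downstream users can attach the rule's
PPV as the confidence of the proposal. Gene summaries report prioritized
count, protein length, density per 1000 aa and mean scores, rounded half
away from zero to one decimal as in the published table; the default
inclusion rule keeps genes with density ≥ 30 per 1000 aa.

## Extrapolation

Among known pathogenic variants, only a fraction passes the joint rule —
the share of pathogenicity attributable to misfolding (12.5% in the
published analysis: 793 of 6328). If the prioritized VUSs represent the same
fraction of the pathogenic VUSs yet to be found, the remainder is
`estimateRemainingUnrelated(n, f) = round(n(1-f)/f)`:

```{r}
estimateRemainingUnrelated(3456, 0.125)
```

Reproducing the published 24,192 requires the *rounded* printed fraction
0.125; the exact fraction 793/6328 gives 24,122. Both modes are available;
new analyses should pass the exact fraction from `misfoldingFraction()`.

## Structural features

`readProteinModel()` reads fixed-column PDB (first model, altloc blank/'A'),
takes per-residue confidence from the B-factor column (the pLDDT convention
of predicted structures) and remaps residues to a contiguous 1-based index.
Features used by the analysis:

* **SASA** — Shrake–Rupley quadrature with golden-spiral test points
  (default 960 per atom) and a 1.4 Å water probe, over a fixed element
  radius table (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Å). Percent SASA
  normalizes by the theoretical Gly-X-Gly maximum ASA per residue type
  (Tien et al. 2013), clamped to 100. The original analysis does not state
  its SASA algorithm or normalization; these are conventional choices and
  the reference table is configurable in the one place it is defined.
* **Clash score** — overlaps (r_i + r_j − d ≥ 0.4 Å) per 1000 atoms, with
  same-residue and adjacent-residue pairs excluded as bonded proxies. This
  is an intentionally simplified quality signal, not a reimplementation of
  dot-based all-atom contact scoring; numeric agreement with MolProbity
  clashscores is a non-goal.
* **Confidence bins** — boundaries follow the published column headings
  with 50 and 70 assigned to the upper bin of each pair and 90 to 70–90
  (">90" strict); the source tables do not state boundary handling, so the
  convention is fixed here and tested as a partition.
* **Domain overlap** — BED-style half-open 0-based intervals on protein
  coordinates; membership of 1-based residue i tests coordinate i−1.

`generateToyStructure()` supplies an ideal poly-alanine helix (rise 1.5 Å,
100°/turn; consecutive Cα–Cα ≈ 3.83 Å) with span-controlled confidence so
the geometric operators have fixtures with known answers.

## Numerical choices and edge cases

* Undefined rates (0/0 PPV when nothing passes) are `NA`, never 0 or 1.
* Percentages, densities and mean scores in reports are rounded half away
  from zero to one decimal, matching the published tables; base R's
  round-half-to-even is not used for reported values.
* The SASA quadrature error decreases with point count; at 960 points the
  total SASA of random 5–30 atom configurations agrees with an independent
  Monte-Carlo oracle within 3% (tested).
* `findCaddCutoff()` returns `NA` both when no classified variant passes
  the ΔΔG cutoff and when no candidate attains the target PPV; callers
  distinguish failure from a legitimate cutoff by `is.na()`.
* Empty variant tables, empty domain tracks, single-residue structures and
  zero class counts are all defined, tested cases.

## Problem sizes

The test suite runs the full 128,167-variant cohort for calibration checks
(a few seconds) and smaller cohorts (hundreds to a few thousand rows)
elsewhere; SASA property tests use 5–30 atom configurations where the
Monte-Carlo oracle is exact enough to be discriminating. The acceptance
script averages the calibration metrics over 25 replicate cohorts of the
two calibration classes (8053 variants each), which bounds the Monte-Carlo
standard error of the reported PPV well below the comparison tolerance.

## Known limitations

* The generator's Gaussian copula cannot represent tail dependence between
  ΔΔG and CADD; the calibrated thresholds are reproduced by construction of
  the marginals, not evidence of real-data performance.
* ΔΔG_Fold only addresses misfolding. Variants pathogenic through binding
  disruption, splicing, or post-translational modification sites are
  invisible to the rule — that is exactly what the extrapolation step
  quantifies.
* One protein length per gene: isoform-specific lengths beyond the
  configured canonical one are out of scope.
* The clash score is a QC heuristic; no rotamer, Ramachandran or
  hydrogen-placement analysis is performed.
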
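Package: foldvus
Title: Prioritizing Variants of Uncertain Significance by Predicted Protein Destabilization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for prioritizing missense variants of uncertain significance
    (VUS) in disease gene panels by combining predicted folding free energy
    differences (ddG_Fold, kcal/mol) with CADD deleteriousness scores.
    Implements the thermodynamic link between ddG_Fold and the folded:unfolded
    equilibrium, confusion-matrix calibration of joint score thresholds against
    expert-classified variants, structural feature curation from predicted
    protein models (per-residue confidence, Shrake-Rupley solvent accessible
    surface area, domain overlap, a simplified steric clash score), gene-level
    summaries of prioritized variants, and extrapolation of the pathogenic
    burden unrelated to misfolding. A synthetic cohort generator with
    class-conditional bivariate score distributions makes the full pipeline
    testable without access to curated variant databases or structure
    prediction tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
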
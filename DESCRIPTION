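Package: hlapocket
Title: Pocket-Residue Association Analysis for HLA Class II Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fine-mapping toolkit for HLA class II case-control studies that
    works at the level of amino-acid residues in the peptide-binding pockets
    of the DP (and DQ) heterodimer.  Provides two-field allele parsing and a
    packaged registry of allele-to-residue, binding-pocket, rs9277534
    expression-SNP and T-cell-epitope (TCE) group maps; chromosome-based
    frequency estimation with Wald intervals; additive-model logistic
    association with per-gene Bonferroni families; two-locus EM haplotype
    frequency estimation for DPA1~DPB1 and DQA1~DQB1 with chi-squared
    haplotype tests; an opposing-directionality screen that nominates pocket
    residues from protective versus susceptible alleles and haplotypes;
    phase-aware alpha+beta pocket-combination dosages; linkage-disequilibrium
    (D, R squared) analysis between chromosome-level binary features; and a
    synthetic cohort generator that emulates the statistical structure of a
    real atopic-dermatitis study cohort so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
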
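Package: kernpred
Title: Multi-Kernel Pedigree and Genomic Prediction for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multi-kernel prediction of line performance in
    multi-environment plant breeding trials. Builds the pedigree numerator
    relationship matrix (A), the genomic relationship matrix (G = XX'/p from
    standardized markers), and observation-level interaction kernels formed
    as Hadamard products with the environment incidence structure (AxE, GxE,
    GxA, GxAxE). Eight registered reaction-norm models combining these terms
    are fitted by Gibbs sampling with scaled-inverse-chi-square priors and
    missing-phenotype augmentation, yielding variance components,
    percent-of-variance partitions, and predictions for unobserved lines.
    Includes the CV1 random cross-validation and leave-one-year-out (V00)
    validation schemes scored by weighted Pearson correlation, and a
    breeding-pipeline simulator (pedigree, gametic marker inheritance,
    single-year phenotyping) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
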
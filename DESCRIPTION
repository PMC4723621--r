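Package: metabofuse
Title: Multi-Platform Metabolomics Fusion and Double Cross-Validated PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses feature tables from complementary metabolomics platforms
    (GC-MS, 1H-NMR, direct-infusion MS, GC-TOF-MS, ICP-MS) into a single
    autoscaled matrix and identifies class-discriminating variables with a
    double (two-nested leave-one-out) cross-validated PLS-DA, permutation
    testing of the misclassification count, and rank-product summarisation
    of regression coefficients across the cross-validation models.
    Includes the platform-specific preprocessing rules (signal-to-noise
    randomisation, prevalence filtering, spectral bucketing, reference and
    total-intensity normalisation, blank-based limit-of-detection
    filtering), PCA with cross-validated component selection, Ward
    hierarchical clustering with Newick export, and a synthetic-data
    generator that emulates a multi-platform rice-grain study design for
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
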
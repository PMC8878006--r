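Package: crossmet
Title: Multilevel Sparse PLS-DA Analysis of Crossover-Design Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing LC-MS feature tables from crossover-design
    intervention studies. Provides preprocessing (consensus matching of
    peak-picker outputs, probabilistic-PCA missing-value imputation,
    probabilistic quotient normalisation against a pseudo-reference sample,
    and QC-based locally weighted signal-drift correction), crossover
    variance decomposition with one- and two-factor multilevel sparse
    partial least squares discriminant analysis (ML-sPLS-DA),
    cross-validated tuning, VIP and R2/Q2 model performance, candidate
    metabolite selection with FDR-corrected paired tests and fold changes,
    and formula-based ion annotation (monoisotopic mass, adduct m/z, ppm
    error, ring-and-double-bond equivalents). Includes a synthetic
    crossover-study generator with a known variance decomposition so the
    whole pipeline is testable end to end.
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
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
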
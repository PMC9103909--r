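Package: SERSelect
Title: Variable-Selection PLS Calibration for Quantitative SERS Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric calibration pipeline for quantifying analyte
    concentrations (carbendazim residue as the worked case) from
    surface-enhanced Raman scattering (SERS) spectra. Provides a seeded
    synthetic-spectrum generator emulating a seven-level, 36-replicate SERS
    calibration design, multiplicative scatter correction (MSC), a
    rank-stratified 2:1 calibration/prediction split, PLS1 regression with
    cross-validated latent-variable choice, and four wavelength-selection
    algorithms (genetic algorithm, iVISSA, LASSO, and bootstrapping soft
    shrinkage), together with RMSEP/RPD model reports, spike-recovery
    statistics, and a specificity check on baseline-corrected peak
    intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
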
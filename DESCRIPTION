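Package: peptideBOSS
Title: Bitter-Peptide QSAR with Integrated Amino-Acid Descriptors and
    Bootstrapping Soft Shrinkage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling of
    bitter-tasting short peptides (lengths 2-4). Peptide sequences are encoded
    position-wise with a registry of amino-acid descriptor scales (z-scales,
    VHSE, DPPS, FASGAI, HESH and others; 87 parameters per residue when all 14
    canonical sets are active), and bitterness activity log10(1/T) is modelled
    by partial least squares (PLS1) regression with autoscaling and automatic
    component selection by cross-validated Q2. Variable selection uses the
    bootstrapping soft shrinkage (BOSS) algorithm: iterated weighted bootstrap
    sampling of variable space, ranking of bootstrap submodels by RMSECV, and
    coefficient-derived reweighting until a single variable remains. Repeated
    BOSS runs yield selection frequencies that, combined with standardized
    regression coefficients of the best model, quantify variable importance.
    A synthetic-data module generates peptide datasets with known sparse
    signal for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Regression, FeatureExtraction, Cheminformatics
NeedsCompilation: yes
RoxygenNote: 7.3.3
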
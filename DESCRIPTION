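Package: metabocc
Title: Two-Step Case-Control Analysis of Untargeted and Targeted Metabolomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-group (case-control) analysis of LC-MS metabolomics
    feature tables: QC dilution-series calibration and probabilistic quotient
    normalization, PCA-based sample outlier detection with Hotelling T2 and Q
    statistics, normality-gated univariate testing with Benjamini-Hochberg
    false discovery rate control, PLS-DA fitted by NIPALS with post-transformation
    into a predictive and orthogonal score space, VIP-based bootstrap stability
    selection with a permutation-calibrated threshold, Matthews correlation
    coefficient assessment under five-fold cross-validation and permutation
    testing, adduct-aware metabolite annotation against a bundled miniature
    mass table, and hypergeometric pathway over-representation analysis.
    A synthetic-data module generates feature tables, QC dilution series and
    clinical covariate tables with the statistical structure the pipeline
    assumes, so every stage can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), mixOmics, MASS, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
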
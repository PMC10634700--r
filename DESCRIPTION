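Package: spatialTME
Title: Single-Cell Spatial Proteomics Analysis of the Tumor Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing multiplex immunohistochemistry (mIHC)
    single-cell spatial data from tissue regions of the tumor
    microenvironment. Implements declarative hierarchical gating into
    exclusive cell lineages and states, 10-marker T cell functionality
    barcoding, cell state density and radius-based cell-cell spatial
    interaction quantification, recurrent cellular neighborhood (RCN)
    analysis by K-means clustering of neighborhood compositions,
    leave-one-patient-out elastic-net classification of treatment status
    and disease-free survival with exact linear SHAP interpretation, and
    group-difference testing with Benjamini-Hochberg correction. Includes
    a synthetic cohort generator with planted cohort and survival effects
    so the whole pipeline can be exercised and validated without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
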
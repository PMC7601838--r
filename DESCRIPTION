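Package: radiris
Title: Multiparametric Radiomics and Informatics for Imaging-Based Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying tumors into recurrence-risk groups from
    co-registered multiparametric MRI and clinical descriptors. Implements
    single-parameter radiomics (first-order, gray-level co-occurrence,
    run-length and neighborhood gray-tone difference statistics, fractal and
    convexity shape measures, and sliding-window radiomic feature maps),
    multiparametric tissue-signature radiomics (signature probability,
    first-order and co-occurrence features), an unsupervised multi-subspace
    Isomap embedding and clustering engine with a heatmap risk model, a
    correlation-based parameter interaction network with centrality and hub
    analysis, and a hybrid Isomap plus support-vector-machine classifier with
    class-imbalance penalties, leave-one-out cross-validation and ROC
    analysis. A synthetic multiparametric breast-MRI phantom cohort generator
    emulating three OncotypeDX-style risk groups makes the full pipeline
    runnable and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    e1071,
    pROC,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
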
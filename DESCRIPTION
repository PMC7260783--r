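Package: qaffp
Title: QSAR-Derived Affinity Fingerprints with Conformal Applicability
    Domains
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds panels of per-assay random forest QSAR regression
    models from curated bioactivity data, wraps each model in a
    conformal predictor so that prediction-interval width defines an
    applicability domain, and emits real-valued and binarized affinity
    fingerprints for arbitrary molecules. Includes the evaluation
    harnesses used to benchmark such fingerprints: similarity searching
    with MAX group fusion, balanced random forest bioactivity
    classification, and Bemis-Murcko cyclic-skeleton scaffold hopping,
    together with exact paired Wilcoxon comparisons and a synthetic
    data generator with planted structure-activity signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    ranger,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: OpenBabel (the obabel executable must be on the PATH)
biocViews: Cheminformatics, Regression, Classification
RoxygenNote: 7.3.3
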
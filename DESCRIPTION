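Package: octaco
Title: Retinal OCT Image Classification with Deep Features and Ant Colony
    Optimization Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for multiclass classification of retinal optical
    coherence tomography (OCT) B-scans across five disease classes
    (age-related macular degeneration, branch and central retinal vein
    occlusion, central serous chorioretinopathy, diabetic macular edema).
    Deep features are exported from the global-average-pool layer of
    modified ResNet-50, DenseNet-201 and InceptionV3 backbones with a
    replaced five-class head; an ant-colony-optimization (ACO) feature
    selector with pheromone/visibility transition rules, local and global
    pheromone updates and correlation-based redundancy pruning reduces the
    feature vector; seven classifier presets are benchmarked under
    stratified ten-fold cross-validation. Includes seeded synthetic
    generators for planted feature tables and stylized OCT-like image
    trees so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    MASS,
    png,
    pROC,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
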
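Package: ugfc
Title: Brain Lesion Detection by Unified Gravitational Fuzzy Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-stage cascade for detecting hyperintense lesions in
    single-slice grayscale MR images. Stage one enhances contrast with a
    three-rule Mamdani fuzzy inference system (min implication, max
    aggregation, centroid defuzzification). Stage two segments the enhanced
    image with unified gravitational fuzzy clustering (UGFC): kernel-density
    mode counting seeds the centroids, confidently classified pixels are
    hard-clustered with a Newtonian gravity rule, and ambiguous pixels keep
    fuzzy C-means memberships. Stage three refines the candidate lesion
    boundary with reinitialization-free level-set evolution driven by an
    edge-indicator field and a distance-regularizing internal energy.
    Includes Dice/Jaccard/sensitivity/specificity evaluation, a seeded
    synthetic head-phantom generator with known lesion ground truth, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
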
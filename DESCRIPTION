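Package: wcbaseg
Title: Dictionary-Based Deformable Lung Tumor Segmentation with a Water
    Cycle Bat Optimizer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation of lung tumors in 2-D CT slices by a
    dictionary-based deformable model. The pipeline median-filters the
    slice, extracts the lung lobes by Bayesian fuzzy clustering, and
    delineates the tumor with a multi-label level set driven by texture
    probabilities from a k-means patch dictionary; the curve update can be
    modified by a hybrid water cycle / bat metaheuristic, which is also
    exposed as a standalone box-constrained optimizer. Includes a seeded
    synthetic lung-phantom generator with exact ground-truth masks and the
    standard overlap metrics (accuracy, Jaccard, Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
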
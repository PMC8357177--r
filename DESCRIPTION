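Package: emsm
Title: Speed-Invariant Gait Recognition with the Enhanced Mutual Subspace Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of subjects from binary gait-silhouette sequences
    that is robust to walking-speed changes. Each gallery class and each probe
    is modelled as a linear subspace of image space and compared through the
    squared cosines of the canonical angles between subspaces (the mutual
    subspace method, MSM). The enhanced MSM adds two-dimensional PCA image
    bases per gallery class, a bank of in-plane image rotations, and AdaBoost
    fusion of the weak classifiers indexed by canonical-angle order, subspace
    dimensionalities and rotation angle. Includes silhouette sequence I/O and
    normalization, gait-cycle estimation, gait energy images, a parametric
    articulated-walker generator for fully synthetic benchmarks, and biometric
    evaluation metrics (CCR, ROC, EER, specificity/sensitivity sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
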
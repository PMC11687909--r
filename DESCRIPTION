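Package: macmot
Title: Morphology and Motility Profiling of Macrophage Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies single-cell morphology and motility from segmented
    label-mask time-lapse microscopy of macrophages and links both to
    polarization state (M0/M1/M2). Provides per-cell shape descriptors
    (compactness, eccentricity, solidity, size), trajectory metrics (speed,
    persistence, trajectory convex-hull area), principal shape-mode analysis
    of arc-length-resampled cell outlines, k-means morphology clustering with
    silhouette-based model selection, quadratic discriminant analysis of
    cluster separation in speed-persistence space with Gaussian-process
    time-course smoothing, and a SMOTE-balanced RBF-kernel SVM subtype
    classifier under stratified cross-validation. Includes a synthetic
    label-mask generator with three motility-coupled morphological archetypes
    so that the full pipeline is testable without real microscopy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    cluster,
    e1071,
    jsonlite,
    pracma,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse,
    png,
    withr,
    knitr
Config/testthat/edition: 3
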
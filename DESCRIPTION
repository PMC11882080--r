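Package: actinwave
Title: Inference of Cellular Microenvironment from Actin-Wave Video Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Feature learning and classification pipeline for fluorescence
    time-lapse videos of actin polymerization waves in giant Dictyostelium
    discoideum cells. Extracts static per-frame features by sparse dictionary
    learning on image patches and by a first-order Morlet wavelet scattering
    transform, and dynamic per-video features by Shi-Tomasi corner detection
    with pyramidal Lucas-Kanade optical flow. Linear support-vector machines
    on these features classify each frame or video by surface nano-topography
    (flat versus ridged) and by the presence of an external DC electric field.
    Includes a synthetic video generator that emulates quasi-one-dimensional
    ridge-guided waves, isotropic two-dimensional wavefronts, and field-driven
    drift, so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    e1071
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Classification, Software
RoxygenNote: 7.3.3
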
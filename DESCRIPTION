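Package: nvpipe
Title: Neurovascular Imaging Quantification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification chain for awake-mouse neurovascular imaging studies:
    vessel diameter time series from two-photon movies by full-width-half-maximum
    profiling perpendicular to a vessel skeleton, red blood cell velocity from
    line-scan kymographs by radon-style projection variance maximisation,
    stimulus-locked trial segmentation with locomotion gating and 2-SD
    responsiveness classification, vasomotion power spectral analysis at 0.1 Hz,
    CMRO2 and rest-period haemodynamic baselines, calcium ON/OFF/BOTH cell
    classification and the neurovascular coupling index, ex vivo vascular
    morphometry (3D skeletonisation, distance-map radii, pericyte density,
    diameter versus soma distance), home-cage activity quantification from pose
    tracking tables, and Fisher-Z correlation plus PCA preparation statistics.
    A synthetic-data module generates every input with known ground truth so the
    whole chain is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
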
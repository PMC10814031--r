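Package: needleplan
Title: Automatic Needle Path Planning for CT-Guided Thermal Ablation of Lung Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans percutaneous ablation needle trajectories on labeled
    thoracic CT volumes. Candidate insertion points are enumerated on the
    bounding-box surface (one sight line per boundary voxel), filtered by four
    hard clinical constraints (organ avoidance, needle length, pleural entry
    angle, insertion depth), scored by three grayscale soft-constraint maps
    built from 3D Euclidean distance transforms and per-ray minimum/maximum
    projections, and ranked by Pareto-front intersection with weighted
    aggregation. Includes a deterministic analytic thorax phantom generator
    with an exact geometric occlusion oracle for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
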
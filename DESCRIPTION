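Package: bonetrace
Title: Entropy-Based Segmentation and Fracture Detection for Long-Bone Radiographs
Version: 0.1.0
Authors@R:
    person("bonetrace", "maintainers", email = "maintainers@bonetrace.invalid",
           role = c("aut", "cre"))
Description: A hybrid pipeline for paediatric forearm radiographs: PCA-based
    rotation alignment of the collimation field, sigma-weighted local Shannon
    entropy maps for tissue removal, row-wise line-edge detection, region of
    interest extraction around the ulna and radius, graph-based bone contour
    tracing, and fracture detection by polynomial-regression contour deviation.
    Includes a synthetic forearm phantom generator with known ground truth,
    entropy-based segmentation quality metrics, confusion-matrix evaluation
    tooling, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
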
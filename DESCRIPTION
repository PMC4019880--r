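Package: stereobench
Title: Benchmarking Automated 3D Cell Detection Against Stereologic
    Counting Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An evaluation pipeline for automated three-dimensional cell
    detection in thick-section microscopy. Generates synthetic image
    stacks with exactly known ground truth emulating four acquisition
    conditions (widefield and confocal fluorescence, spinning disc, and
    brightfield DAB), runs a baseline threshold/connected-components/
    size-filter detector, scores detections against ground-truth
    centroids using a cylindrical matching tolerance with
    interior/boundary stratification and multi-method combination, and
    implements the unbiased 3D stereologic counting rules (counting
    frame, top-of-cell rule, fractionator estimate) that centroid-based
    detection is contrasted with.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
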
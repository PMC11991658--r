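Package: leafmvs
Title: Edge-Aware Multi-View Stereo Reconstruction and Evaluation for Plant Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for edge-aware multi-view stereo (MVS) reconstruction of
    plants from calibrated RGB images: Canny edge extraction and four-channel
    (R, G, B, Edge) input construction, focal and edge-aware training losses
    over discretized depth hypotheses, geometric-consistency depth-map fusion
    into point clouds, depth-map and point-cloud accuracy/completeness metrics,
    leaf-edge segmentation via surface meshing, and phenotypic trait extraction
    (leaf area, plant height) with agreement statistics. Includes readers and
    writers for MVSNet-style camera files, PFM depth maps and PLY point clouds,
    plus a deterministic synthetic plant-scene generator (camera ring, rendered
    ground-truth depth maps) so the full pipeline can be exercised end to end
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
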
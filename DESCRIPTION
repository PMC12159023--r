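Package: pikathresh
Title: Disturbance Thresholds and Health Indices for Pika-Affected Alpine Grasslands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the response of alpine meadow and alpine
    steppe vegetation communities to plateau pika (Ochotona curzoniae)
    disturbance from plot/quadrat survey data.  Builds a composite grassland
    health index from min-max standardized community indicators with
    PCA-derived weights (with Kaiser-Meyer-Olkin and Bartlett sphericity
    diagnostics), classifies plots into four disturbance levels by Ward
    hierarchical clustering, extracts diversity-density disturbance
    thresholds from loess response curves with a conservative adoption rule,
    computes relative change rates along the burrow-density gradient, and
    provides the supporting spatial and permutation statistics: haversine
    distance matrices, distance-based Moran's eigenvector maps (dbMEM),
    Moran's I, seeded permutation Mantel tests, and Wilcoxon rank-sum
    comparisons.  A seeded synthetic survey generator emulating the
    plot/quadrat design makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
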
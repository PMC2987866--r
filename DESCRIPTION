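Package: morphid
Title: Landmark-Based Geometric Morphometrics for Cryptic Species
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying cryptic insect species from 2-D
    anatomical landmark configurations. Implements Generalized Procrustes
    superimposition with centroid size and tangent-space coordinates,
    thin-plate-spline partial and relative warps, Procrustes-distance and
    canonical-variate (Mahalanobis) classification of unknown specimens
    against reference species using a one-by-one supplementary protocol,
    ANOVA-based digitization repeatability for quantifying the measurement
    error introduced when different users digitize the same specimens, and
    a fully seeded synthetic landmark generator with known ground truth.
    Reads and writes TPS landmark files and plain coordinate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
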
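Package: denticode
Title: Standardized Character Coding and Disparity Analysis for Shark
    Dermal Denticles
Version: 0.5.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a versioned morphological character-coding system
    for elasmobranch dermal denticles: a 46-trait schema with per-trait
    state-distance matrices and disparity weights, specimen coding-sheet
    input/output with range and nesting validation, missing-data-aware
    weighted pairwise disparity with per-pair normalization over the
    shared codable traits, morphotype identification with near-duplicate
    merging, non-metric multidimensional scaling of the resulting
    morphospace, and a synthetic-data generator for coded specimens,
    morphotype clusters and taphonomically degraded ("broken") codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    MASS,
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
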
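Package: chumap
Title: Mapping PedsQL 4.0 Scores onto CHU-9D Health Utilities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates Child Health Utility 9D (CHU-9D) utilities from
    Pediatric Quality of Life Inventory (PedsQL 4.0) responses. Scores both
    instruments, fits six mapping estimators (ordinary least squares, a
    logit-link generalized linear model, robust MM regression, upper-censored
    Tobit regression, Beta regression, and multinomial-logit response
    mapping) over six variable combinations, ranks them with ten-fold
    cross-validated error metrics, and ships a published crosswalk
    coefficient table for direct application to new PedsQL data. A seeded
    synthetic-cohort generator reproduces the joint statistical structure of
    paired-instrument pediatric samples for simulation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
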
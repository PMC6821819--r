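Package: trophnet
Title: Spatiotemporal Analysis of Trophallactic Networks in Ant Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mouth-to-mouth food-exchange (trophallaxis)
    networks recorded by scan sampling in ant colonies. Builds directed,
    weighted exchange networks from per-minute contact scans, classifies
    foragers by feeding visits, and quantifies activity heterogeneity
    (Lorenz curves, Gini coefficients), network structure (centralities,
    global efficiency, pair-type shares), temporal spreading (naive-ant
    survival, exponential onset fits, T50 quantiles), and spatial
    organisation (gravity centres, occupancy grids, entrance-distance
    drift). Includes edge-rewiring and time-permutation reference models
    with Z-tests, Poisson-GLM overdispersion tests of inter-individual
    heterogeneity, and a synthetic colony generator with exposed ground
    truth for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
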
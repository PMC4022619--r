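Package: aguadas
Title: Waterhole Network Connectivity Under Drought Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the connectivity of seasonal waterhole
    ('aguada') networks in drought-prone landscapes. Extracts
    species-specific spatial graphs from a waterhole layer by linking
    centroids within a movement-distance threshold, applies area-ordered
    drought deletion scenarios, and quantifies connectivity through link
    density, connected clusters, the probability-of-connectivity (PC)
    numerator under a negative exponential dispersal kernel, and
    patch-removal node importance (dPC). Also computes waterhole-associated
    suitable habitat as buffer unions around waterhole footprints, and
    simulates clustered waterhole landscapes with power-law size structure
    so the full pipeline can be exercised and validated without field
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    polyclip,
    sp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
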
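Package: riparify
Title: River Network Restoration Prioritization and Vector Landscape Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria restoration prioritization for attributed river
    networks, together with a class-level vector landscape-metrics engine and
    riparian-buffer land-cover composition analysis. Each river segment is
    scored on four 0-2 point criteria (migration barriers, ecomorphological
    condition, national priority species, aquatic-diversity hotspots), with a
    500 m along-network adjacency rule, weighted aggregation onto a 0-8 scale
    and a five-class priority categorization; restored and data-deficient
    segments are reported as their own categories. Land-cover mosaics are
    validated against a minimum mapping unit, dissolved into patches and
    summarized with NP, MPS, ED, MNND and MSI plus epoch-to-epoch change
    tables. All geometry is planar-metric and vector-native; seeded synthetic
    generators for networks and mosaics make every analysis reproducible
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
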
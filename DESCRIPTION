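Package: metapatch
Title: Species-Patch Metacommunity Networks and Temporal Beta Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing waterbird-habitat patch metacommunities as
    bipartite species-patch networks across hydrological periods. Builds
    per-period occurrence networks from long-format survey tables, computes
    network-level metrics (connectance, NODF nestedness, Barber bipartite
    modularity) and node-level metrics (degree, nestedness contribution,
    coefficient of variation), and partitions the temporal beta diversity of
    species-patch links between periods into extinction/colonization and
    local/regional/landscape/regional-landscape components. Includes classic
    diversity indices (Shannon-Wiener, Pielou evenness, Bray-Curtis),
    hydrological covariate utilities (inundation duration and classes, regime
    labelling, shoreline-development shape index, NDVI), and a seeded synthetic
    metacommunity generator that emulates river-connected patches responding to
    four hydrological regimes beside stable surrounding lakes, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
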
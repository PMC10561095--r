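Package: epirisknet
Title: Regional Epidemic Risk Classification on Directed Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies regions of a new epidemic area into high, medium and
    low risk levels by modelling inter-region social connections as a
    directed weighted scale-free network. Inter-region correlation strengths
    are derived from multiple raw indicators (distance, personnel flow,
    economic traffic, transport convenience, logistics intensity) with the
    CRITIC objective weighting method, risk values are propagated outward
    from outbreak source regions over a layered orientation of the network
    using single-parent and multi-parent attenuation rules with a dedicated
    treatment of same-layer loop nodes, and every region is assigned a
    three-level risk grade under configurable thresholds. Includes a seeded
    preferential-attachment network generator, a synthetic indicator-data
    generator, two bundled 50-region benchmark networks with reference
    classifications, and plain-text readers and writers for edge lists,
    indicator tables and risk reports.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
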
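Package: hubfail
Title: Targeted Hub-Attack Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying how functional brain networks
    reorganise when their most central region fails. Binary networks are built
    from region-by-time series by Pearson correlation and thresholding, the
    attack target is selected by eigenvector centrality, node failure is
    simulated with the Crucitti-Latora-Marchiori (CLM) load-capacity cascade,
    and the topological consequences are quantified by the clustering
    coefficient, global efficiency, and normalised rich-club statistics
    (rich, feeder, and local connections) compared across two subject groups
    with FDR-corrected tests. A synthetic-cohort generator emulates a
    patient/control study with a planted rich-club deficit so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
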
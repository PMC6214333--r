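Package: eegfu
Title: Functional Unit Detection in Multichannel EEG Coherence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions multichannel EEG coherence networks into spatially
    connected functional units (FUs). Implements magnitude-squared coherence
    estimation from segmented recordings, the analytic coherence significance
    threshold for L averaged segments, Voronoi spatial adjacency over electrode
    layouts, and three data-driven FU detection methods: community clique
    detection by spatially constrained modularity optimization (CCB),
    Voronoi-connected maximal clique enumeration with total-strength
    assignment (MCB), and an improved graph watershed with clique-constrained
    flooding and basin merging (IWB). FU maps (Voronoi-cell renderings with
    within- and between-FU coherence summaries) are produced as SVG or PNG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
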
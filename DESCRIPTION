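Package: reservoirnet
Title: Co-Occurrence Network Analysis of Nutrient-Stimulated Reservoir Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares microbial co-occurrence networks from OTU count
    tables along a two-stage nutrient-injection design, as used in indigenous
    microbial enhanced oil recovery (IMEOR) studies. Provides abundance
    preprocessing (relative-abundance filtering, rarefaction, alpha diversity),
    all-pairs Spearman correlation with Benjamini-Hochberg FDR edge calling,
    network topology summaries (nodes, edges, average degree, density,
    negative-edge fraction), betweenness centrality, network robustness under
    random node removal, nutrient-OTU bipartite networks, and high- versus
    low-nutrient stage comparisons. A synthetic community generator with
    planted correlation blocks and port-lagged nutrient curves supplies ground
    truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    vegan,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
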
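Package: netbackbone
Title: Community-Aware Backbone Extraction for Weighted Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts backbones of weighted undirected networks using the
    overlapping community structure. Two node-based filters are provided: the
    overlapping-nodes ego backbone (overlapping nodes plus their one-step
    neighbours) and the overlapping-nodes-and-hubs backbone (overlapping nodes
    plus the top strength-ranked nodes), both pruned of their weakest links
    under a connectivity constraint and cut to a target size. The disparity
    filter of Serrano, Boguna and Vespignani is included as a calibrated
    baseline, together with the overlapping community detector SLPA
    (Speaker-Listener Label Propagation), a planted-overlap synthetic
    benchmark generator, and a suite of backbone similarity and effectiveness
    measures (common-node proportion, top-rank overlap, rank-biased overlap,
    Pearson and Kendall correlation, mean betweenness / strength / link
    weight).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph (>= 1.5),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
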
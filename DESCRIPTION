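Package: proteoformnet
Title: Gene- and Proteoform-Centric Interactome Networks from Pathway
    Knowledgebases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds gene-centric and proteoform-centric molecular interaction
    networks from flattened pathway-knowledgebase reaction participant tables,
    under three representations of small molecules (excluded, one global node
    per molecule, or one reaction-unique node per molecule and reaction).
    Provides pathway-specific subnetworks via recursive pathway closure, a
    battery of topological summaries (connected components, isolated nodes,
    articulation points, bridges, class-stratified degree statistics),
    link-percolation robustness curves, and a synthetic reaction-table
    generator with planted ground truth so every pipeline stage can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
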
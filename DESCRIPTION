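Package: setviews
Title: Multi-View Set Comparison: Venn, Euler, UpSet, Flower and Network Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the exclusive-region partition of any number of named
    sets (genes, metabolites, OTUs/ASVs) from standardized two-column
    membership tables, pasted element lists, or "&"-signature intersection
    count tables, and renders the partition as classic or Edwards Venn
    diagrams (2-6 sets), area-proportional Euler diagrams (2-3 sets),
    UpSet intersection matrices (3-40 sets), flower plots, and bipartite
    set-element networks. All diagrams are built as renderer-agnostic
    scene graphs exportable to SVG; per-region element lists are written
    as CSV, and pairwise overlap significance is assessed with the
    hypergeometric test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, tools, igraph, jsonlite
Suggests: testthat (>= 3.0.0), xml2, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'signatures.R'
    'setcore.R'
    'cases.R'
    'scene.R'
    'svg.R'
    'overlap-test.R'
    'colors.R'
    'network.R'
    'flower.R'
    'upset.R'
    'template-constants.R'
    'templates.R'
    'venn-scene.R'
    'euler.R'
    'io.R'
    'cli.R'
    'generate.R'
    'setviews-package.R'
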
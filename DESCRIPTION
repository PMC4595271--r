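Package: grapeterp
Title: Integrated Transcriptome-Metabolome Analysis of Grape Berry Terpenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the combined transcriptome-metabolome workflow used to
    nominate terpene-pathway candidate genes in developing grape berries across
    contrasting growing regions. Covers replicate-free digital gene expression
    (proportional multi-read rescue, RPKM, exact conditional binomial testing
    with Bonferroni control), GC-MS internal-standard semi-quantification with
    odor activity values and Duncan's multiple range test, developmental trend
    clustering (row scaling, hierarchical and k-means clustering, trend
    classification), gene-metabolite Pearson correlation with a cumulative
    expression mode, signed thresholded co-expression networks with anchor
    genes (Cytoscape SIF/GraphML export), 2^-dCT qPCR validation against RPKM,
    phenophase climate summaries, and a seeded synthetic-data generator
    emulating the two-region, two-year, four-stage berry sampling design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
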
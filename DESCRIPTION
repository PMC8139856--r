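Package: atlasalign
Title: Cross-Species Single-Cell Atlas Alignment via Homology-Graph Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns single-cell transcriptomic atlases between evolutionarily
    distant species. A weighted bipartite gene-homology graph built from
    reciprocal BLAST bit scores translates expression features between
    species; cells are embedded in a joint principal-component space and
    linked by mutual nearest cross-species neighborhoods computed with a
    graph-coarsening kernel. Cross-species expression imputation then
    reweights the homology graph by expression correlation, and the
    alignment is iterated. Downstream statistics include cell-type
    alignment scores, enriched homologous gene pairs, paralog-substitution
    detection with age-stratified rates, cell-type-graph transitivity with
    bootstrap nulls, hypergeometric term enrichment, and one-to-one
    ortholog selection by maximum-weight bipartite matching. A synthetic
    paired-species atlas generator with ground-truth homology and planted
    paralog substitutions supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
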
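Package: phylobin
Title: Taxonomy-Independent Phylotypes from Phylogenetic Placements of 16S ASVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bins 16S rRNA amplicon sequence variants (ASVs) into
    taxonomy-independent phylotypes from their phylogenetic placements
    (jplace format). Provides the Kantorovich-Rubinstein (earth mover)
    distance between placement mass distributions under the reference
    tree's path metric, a divide-and-conquer agglomerative binning
    algorithm (pre-grouping by shared placement edges, merging pre-groups
    by lowest-common-ancestor separation, exhaustive within-group
    distances), post-hoc integration of newly placed ASVs into an existing
    phylotype set, specimen-by-phylotype count matrices with pseudo-count
    normalization and Bray-Curtis dissimilarity, bounded-best-hit
    recruitment of full-length reference alleles, and a synthetic
    placement generator with binning accuracy metrics (alleles per
    phylotype, phylotypes per allele, rarefaction curves) for in-silico
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
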
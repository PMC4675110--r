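Package: otubench
Title: Evaluation of De Novo and Reference-Based OTU Clustering Methods
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assigning 16S rRNA gene sequences to operational
    taxonomic units (OTUs) and for evaluating the quality and stability of
    the resulting assignments. Implements hierarchical (single, average and
    complete linkage) and greedy centroid (abundance- and distance-based)
    de novo clustering over sparse pairwise distance matrices computed by
    Needleman-Wunsch global alignment or from a shared multiple alignment;
    exhaustive (non-heuristic) closed- and open-reference assignment against
    a reference database; pair-counting confusion matrices and the Matthews
    correlation coefficient for both partition quality (agreement with the
    pairwise distances at a threshold) and partition stability (agreement
    between subsampled and full-data clusterings); threshold scanning,
    hypergeometric rarefaction, reference-order randomization experiments
    and reference-database audits for duplicated sequences with discordant
    taxonomies. A synthetic-community and synthetic-reference-database
    generator with planted ground truth makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Clustering, Microbiome, Sequencing, Metagenomics
RoxygenNote: 7.3.3
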
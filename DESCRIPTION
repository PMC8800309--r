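Package: tadnull
Title: Null Models and Pairwise Gene Similarity Analyses for Topologically
    Associating Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs null models for topologically associating domains
    (TADs): gene-count- and size-matched positional randomisation of TAD
    intervals within chromosomes, within-chromosome gene-identity
    permutation ("random genomes"), and two published comparison
    randomisers. Provides strict-containment gene-to-TAD assignment, CTCF
    boundary classification, A/B compartment assignment, and pairwise
    within-TAD gene similarity metrics (paralogy, expression correlation,
    GO semantic similarity by the Jiang measure with best-match-average
    combination, shared pathways and protein-protein interactions),
    together with median-p ensemble permutation statistics, effect sizes
    and FDR correction. Ships a synthetic-data generator with planted
    effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0),
    GenomicRanges
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
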
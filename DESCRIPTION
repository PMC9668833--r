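Package: diseasome
Title: Disease-Gene Networks, Diseasome Projection and Candidate-Gene Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building disease-gene bipartite networks and projecting
    them to weighted disease-disease networks (diseasomes), with
    gene-shuffling permutation null models for link significance, pathway and
    Gene Ontology homogeneity statistics, the DIAMOnD hypergeometric
    seed-expansion algorithm for candidate (modifier) gene prediction, a
    sliding-window pathway-enrichment boundary criterion, mouse-phenotype and
    tissue-expression screening of candidates, and attribution of newly
    created disease links to individual candidate genes. Includes a synthetic
    data generator with planted pathway coherence and planted interactome
    modules so every stage of the pipeline can be exercised and calibrated
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
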
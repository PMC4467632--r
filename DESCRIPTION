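Package: diseaseflow
Title: Disease-Disease Correlations from Information Flow in Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents heterogeneous disease-protein networks built from a
    protein-protein interaction edge list and disease-gene associations,
    computes per-disease weight vectors as expected visit counts of an
    absorbing random walk (every disease node terminates the walk), scores
    pairwise disease correlations as cosines between weight vectors, fits an
    overlapping probabilistic clustering of diseases, and supports what-if
    edits of a disease's gene associations with fast approximate re-scoring
    accompanied by certified upper bounds on the approximation error. A
    synthetic network generator with planted disease modules supports fully
    reproducible testing without external databases, and a Monte-Carlo walk
    simulator provides an independent check of the linear-algebra solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
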
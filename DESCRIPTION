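Package: mecorank
Title: Patient-Specific Cancer Driver Gene Prioritization by Bipartite
    Network Propagation and Condorcet Aggregation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Prioritizes cancer driver genes from matched somatic mutation and
    expression data. For every tumor sample a bipartite graph is built over a
    protein-protein interaction network, with expression nodes on one side and
    that sample's mutated genes on the other; mutation-damage coefficients
    derived from PolyPhen and SIFT annotations and standardized expression are
    propagated by a damped, degree-normalized iteration until convergence,
    yielding a per-patient gene ranking. Per-patient rankings are then combined
    into a cohort-level driver list with a penalty-modified Condorcet scheme
    completed by Copeland tallies, down-weighting genes that are not mutated in
    a given patient. Includes readers for edge-list, expression-matrix and
    MAF-style mutation files, evaluation against a known-driver list
    (rank-cutoff curves, average precision, sub-sampling robustness), and a
    seeded synthetic-cohort generator with planted drivers for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
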
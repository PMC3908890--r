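Package: nfapin
Title: Noise-Filtered Active Protein Interaction Networks from
    Time-Course Expression
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dynamic (per-time-point) protein interaction
    subnetworks from time-course gene expression and a static protein
    interaction network. Expression profiles are screened for time
    dependence with an autoregressive likelihood-ratio F-test; noisy
    genes (time-independent with low mean) are removed; per-gene
    activity thresholds based on the mean, standard deviation and a
    fluctuation factor determine when each protein is active; each time
    point's subnetwork keeps only interactions between co-active
    proteins. Protein complexes are detected in the subnetworks with
    Markov clustering and evaluated against benchmark complex sets with
    the neighbourhood-affinity overlap score. Includes a seeded
    synthetic-data generator with planted complexes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
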
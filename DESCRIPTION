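Package: netpharm
Title: Network-Pharmacology Target Discovery: Consensus DEGs, MCC Hubs,
    Enrichment and Interactome Proximity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale network-pharmacology pipeline for computational
    target discovery, built around a rheumatoid-arthritis case study.
    Implements consensus differential-expression screening of case/control
    microarray sets with an empirical-Bayes moderated t-statistic,
    construction of a protein-protein interaction subnetwork from scored
    (STRING-style) edge lists, hub identification by maximal clique
    centrality with top-fraction selection and submodule decomposition,
    hypergeometric over-representation analysis against GMT gene-set
    collections with Benjamini-Hochberg and Storey q-values, and the
    interactome separation score S_AB (average shortest-path set
    distances) with its sign-based proximal/separated call,
    indirect-target enumeration, intermediary-protein extraction and
    batch scoring. Ships a synthetic-data module (planted differential
    expression, scale-free interactomes with planted proximal/separated
    target-set pairs) and the study's printed gene lists and docking
    table as plain-text fixtures so the full pipeline runs with no
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
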
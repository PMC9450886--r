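Package: fishclust
Title: Behavioral Phenotyping of Zebrafish Exploration by Graph Clustering and Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four exploratory parameters (bottom distance, center distance,
    distance travelled, percent of tank explored) from three-dimensional novel-tank
    swim traces, clusters fish with a similarity-weighted k-nearest-neighbor graph and
    Louvain community detection, assigns new sessions to reference clusters by
    nearest-neighbor vote, and provides permutation statistics (representation tests,
    longitudinal overlap scores, permutation t-tests and ANOVAs, Benjamini-Hochberg
    FDR, Spearman correlations with bootstrap intervals). Includes a correlated
    random-walk simulator that generates synthetic cohorts with archetype structure,
    strain and sex composition, and session-to-session persistence so the full
    pipeline is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    cluster,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
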
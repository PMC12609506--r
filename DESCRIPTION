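Package: tepnet
Title: Controllability Analysis of Tumor-Educated Platelet Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs signed, directed platelet signaling networks from
    curated interaction tables and differential-expression statistics, and
    prioritizes therapeutic targets in tumor-educated platelets by structural
    controllability. Implements maximum-matching driver-node analysis with
    critical/intermittent/redundant and indispensable/neutral/dispensable
    node classifications, control capacity and control centrality,
    fold-change-weighted shortest-path subnetwork extraction, proximity-based
    gene (Knode) scoring on the expanded interactome, and coverage-based
    ranking of drugs and drug combinations. Includes a seeded generator for
    synthetic interactomes, gene statistics and drug tables so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
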
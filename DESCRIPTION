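Package: taism
Title: DEMATEL-TAISM Structural Modelling of Influence Factor Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns expert-scored pairwise influence judgments among the
    factors of a complex system into a total-influence (DEMATEL) analysis
    and an antagonistic multilevel topological hierarchy (TAISM).
    Implements direct-matrix aggregation, row-column Euclidean-norm
    normalization, the Neumann-series comprehensive influence matrix,
    centrality and cause statistics, mean-plus-sigma interception,
    Boolean reachability with strongly-connected-component condensation,
    transitive-reduction skeletons with loop re-expansion, result-priority
    (UP) and cause-priority (DOWN) level extraction, and influence-valued
    topology export (CSV, JSON, DOT, GraphML). Ships the 13-factor
    adolescent non-suicidal self-injury (NSSI) determinant system as a
    worked fixture and a seeded synthetic expert-panel generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
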
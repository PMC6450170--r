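Package: targettriage
Title: Cross-Tissue Transcriptomic Triage of Druggable Targets
Version: 0.1.0
Authors@R: person("Target", "Triage Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: An in-silico target-prioritization pipeline for two-tissue
    transcriptomic studies: two-group differential expression with fold-change
    and p-value gates, cross-tissue overlap with direction concordance,
    a hypergeometric scan for chromosomal stretches enriched in differentially
    expressed genes ("hot spots"), interactome over-connectivity statistics
    (Actual/Expected/z/p) with one-step network expansion and hub ranking,
    gene-set over-representation with Benjamini-Hochberg adjustment, qPCR
    relative quantification by the 2^-ddCt method, and a multi-criterion
    ranking of membrane-receptor drug targets. Seeded synthetic-data
    generators with planted truth make the whole chain testable without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
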
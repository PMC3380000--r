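Package: bottlenet
Title: Bottleneck Gene Discovery in CLR Coexpression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers coexpression networks from multi-condition time-course
    transcriptomics with the context likelihood of relatedness (CLR)
    algorithm (B-spline mutual information estimation followed by
    background-corrected Z-scores), identifies bottleneck genes as the top
    fraction of nodes ranked by betweenness centrality, condenses networks
    into bottleneck-community summaries with hypergeometric gene-set
    enrichment, intersects bottlenecks across networks with a permutation
    test for overlap significance, and tests regulatory coherence of gene
    neighborhoods on perturbation-response data. Includes a synthetic-data
    generator with planted coexpression modules and bridge genes so the
    whole pipeline can be exercised and scored against a known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
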
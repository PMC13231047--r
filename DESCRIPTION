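Package: comorbhub
Title: Comorbidity Hub-Gene Discovery from Dual-Disease Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for discovering hub genes
    shared between two comorbid diseases from case/control expression cohorts
    and curated disease-association tables. Implements empirical-Bayes
    moderated differential expression with direction-consistent intersection,
    weighted co-expression analysis (soft-threshold scan, topological overlap,
    module detection, eigengene-trait correlation), scored protein-interaction
    network analysis with MCODE complex detection and maximal clique
    centrality ranking, hypergeometric over-representation and ranked
    gene-set enrichment, single-sample enrichment scoring of immune-cell
    signatures, median-split Kaplan-Meier survival stratification, and
    miRNA-mRNA bipartite network construction. A seeded synthetic-data
    generator with planted ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
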
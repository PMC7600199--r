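Package: polyqnet
Title: Cross-Model Network Dynamics of PolyQ Protein Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing transcriptional
    dysregulation across matched cellular and animal models of
    polyglutamine (polyQ) protein aggregation, as in spinocerebellar
    ataxia type-1 (SCA1). Provides differential-expression calling on
    FPKM matrices, rank-filtered ortholog mapping, hypergeometric
    gene-set over-representation with cross-model stage matching,
    stage-specific protein-protein interaction network construction
    with confidence and tissue-expression filters, exact 4-node motif
    censuses with degree-preserving null-model z-scores, centrality
    dynamics (degree, betweenness, closeness) with trajectory-based
    target prioritization, and a drug-target overlay with a strict
    blood-brain-barrier consensus rule. A synthetic-data generator
    with planted ground truth makes the whole pipeline testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
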
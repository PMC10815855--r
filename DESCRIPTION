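Package: sysgen
Title: Systems Genetics of Gene Expression in Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-genetics toolkit for discovering candidate upstream
    regulators of a focal gene in recombinant inbred (RI) panels such as the
    BXD family. Implements Pearson correlation screens against the
    transcriptome and trait panels, likelihood-ratio-statistic (LRS) interval
    mapping at genotyped markers with permutation-derived significant and
    suggestive thresholds, 1.5-LOD support intervals and cis/trans eQTL
    classification, a 0-10 weighted multi-criterion candidate-gene
    prioritization score, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and single-sample gene set enrichment
    (ssGSEA) immune-infiltration scoring with group-wise differential tests.
    Ships a synthetic-data module that simulates RI genotypes under sib-mating
    map expansion, expression with planted cis/trans eQTLs and correlated
    gene blocks, trait panels, and case/control cohorts built from planted
    cell-type signature mixtures, so the whole pipeline is testable end to
    end without external downloads.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
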
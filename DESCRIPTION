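Package: tsrnakit
Title: Identification, Quantification and Target Prediction of tRNA-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for tRNA-derived small RNA (tsRNA) analysis from
    adapter-trimmed small-RNA reads: loading and validating mature tRNA
    references with anticodon coordinates, collapsing and placing reads in
    mature-tRNA space, classifying fragments into tRF-5a/b/c, tRF-3a/b,
    tRF-1, tRF-2 and tiRNA-5/3 by cleavage position, CPM normalisation,
    group-wise expressed sets, differential expression with fold-change and
    Benjamini-Hochberg FDR filters, seed-sequence (positions 2-8) grouping,
    position frequency matrices for sequence logos, 3' UTR seed-match
    scanning with an intermolecular RNA duplex minimum-free-energy dynamic
    programme, Pearson phenotype correlation, and hypergeometric gene-set
    enrichment. Includes a fully seeded synthetic-data generator (reference
    tRNAs, planted fragment catalogs, two-condition FASTQ read sets, and
    3' UTRs with planted target sites) so every pipeline stage can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
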
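Package: ceRNAtriad
Title: Inference of Dysregulated mRNA-miRNA-mRNA Competing Endogenous RNA
    Networks from Paired Bulk Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens paired bulk mRNA/miRNA case-control expression profiles
    for dysregulated competing endogenous RNA (ceRNA) axes of the form
    mRNA-miRNA-mRNA. Implements two-group differential expression with
    fold-change and p-value cutoffs, cross-dataset consensus with direction
    agreement, the hypergeometric shared-miRNA test, signed Pearson
    co-expression screening, ceRNA network assembly and summary,
    hypergeometric over-representation analysis against GMT gene-set
    collections, degree-based hub ranking on interaction edge lists, and a
    synthetic-data generator that plants recoverable ceRNA modules so every
    stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
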
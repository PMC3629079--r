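Package: litriage
Title: Rules-Based Document Relevancy Scoring for Biocuration Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores and ranks PubMed/MEDLINE records for manual biocuration
    of chemical-gene-disease interactions. Recognizes chemicals, genes,
    diseases and molecular action terms in titles and abstracts by
    dictionary lookup against controlled vocabularies, assigns each article
    an integer document relevancy score (DRS) from a 13-rule additive
    algorithm, bins and ranks corpora, and evaluates rankings with mean
    average precision, macro-averaged actor recall, per-bin curation
    metrics and quartile comparisons against a recency (PMID) baseline.
    Includes a seeded generator of synthetic corpora with planted rule
    triggers and curation outcomes for end-to-end testing, and a
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
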
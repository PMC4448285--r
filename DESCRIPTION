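Package: kbharvest
Title: Distant-Supervision Harvesting of Biomedical Relational Facts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for constructing a biomedical knowledge base from
    pre-parsed text and HTML documents. Recognizes dictionary entities in
    token spans by character 3-gram MinHash/LSH candidate retrieval with
    exact Jaccard verification, gathers sentence-level patterns (shortest
    dependency path expanded with negation and modifier dependents) and
    document-structure patterns (title/heading/list-item triples), scores
    mined pattern subsequences by distant supervision against seed facts,
    and accepts a consistent set of weighted fact candidates by type-signature
    filtering plus weighted Max-Sat approximation (dominating unit clause
    preprocessing and Johnson's greedy heuristic). Includes evaluation
    statistics (Wilson score interval with a width stopping rule, Fleiss'
    kappa) and a synthetic-corpus generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
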
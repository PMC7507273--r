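Package: relink
Title: Collective Entity Linking for Biomedical Text with Personalized PageRank
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grounds chemical and disease mentions from annotated biomedical
    text to ontology concepts. Candidate concepts are generated by normalized
    edit-distance matching against ontology names and synonyms, assembled into
    a per-document disambiguation graph whose edges come from the ontology
    is-a structure, from relations extracted from text, or both, and ranked by
    truncated Personalized PageRank coherence weighted by extrinsic
    information content. Includes readers for OBO ontologies, CTD tab-separated
    vocabularies and PubTator corpora, micro-averaged evaluation with
    surface-form deduplication, and a seeded synthetic-data generator for
    benchmarking the whole pipeline without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
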
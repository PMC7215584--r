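Package: autoqsp
Title: Quantitative Systems Pharmacology of Autophagy Modulators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology (QSP) toolkit for analysing
    sets of pharmacological modulators (e.g. autophagy activators, inhibitors
    and dual-modulators) and their protein targets as a bipartite network.
    Provides probabilistic matrix factorization (PMF) for predicting novel
    drug-target interactions from a sparse binary interaction matrix,
    structural (Tanimoto fingerprint) and functional (interaction-pattern
    cosine) drug-drug similarity, hypergeometric over-representation analysis
    of target sets against gene-set collections with Benjamini-Hochberg FDR
    control, and degree/promiscuity summaries of the drug-target network.
    Includes a fully seeded synthetic-data generator that emulates
    DrugBank-like interaction catalogs with planted pathway enrichment, so
    every stage of the pipeline can be exercised and validated without
    licensed external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    ChemmineOB,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
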
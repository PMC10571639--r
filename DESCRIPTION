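Package: vaxnorm
Title: Vaccine Name Normalization Against an Ontology Vocabulary
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for normalizing free-text vaccine names from
    clinical-trial intervention tables to concepts in a vaccine ontology.
    Mines candidate mentions with the registry's SQL predicate semantics,
    ranks candidate concepts with pluggable text encoders (a deterministic
    character n-gram TF-IDF backend ships; transformer encoders plug in
    through the same contract), fuses multiple rankers with weighted
    score, scaled-score, and rank (Borda) ensemble metrics plus a
    string-matching promotion rule, and evaluates with Top-n accuracy and
    an ontology-relational error taxonomy. A seeded synthetic-data
    generator emulates the vocabulary, gold standard, and interventions
    table so the full pipeline runs without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
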
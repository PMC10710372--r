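Package: tblat
Title: Token BLAST-Like Alignment for Fuzzy Ontology Concept Recognition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Recognizes ontology concepts (e.g. Human Phenotype Ontology
    terms) in clinical free text containing typographical errors. Tokens
    are decomposed into overlapping character 3-mers and scored against
    ontology vocabulary tokens with a BLAST-style alignment that sums
    3-mer transition probabilities learned from a corpus of canonical
    token / typo pairs. Scores are interpreted through per-token score
    distributions with length-dependent percentile cut-offs. Includes a
    scoring-matrix builder, a typo taxonomy and classifier, synthetic
    typo and pair-corpus generators, an OBO/OBO-graph lexicon loader
    with a 3-mer inverted index, an entity linker with an exact-match
    baseline, and precision/recall/F1 evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
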
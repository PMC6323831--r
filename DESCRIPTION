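Package: ontorel
Title: Ontology-Aware Relation Extraction from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and classifies relations between biomedical entities
    co-mentioned in a sentence (for example drug-drug interactions) with a
    multi-channel recurrent network in which each candidate entity pair is
    represented by sequences of its ontology ancestors (concatenated and
    common ancestors) alongside word-embedding and WordNet-hypernym
    channels. Includes an OBO ontology loader with ancestor-sequence
    computation and fuzzy entity linking, a reader and writer for the
    SemEval-2013 Task 9 drug-drug interaction XML dialect, a preprocessing
    pipeline (candidate pairs, shortest dependency paths, entity masking,
    negative-instance filtering), a compact LSTM implementation trained
    with Adam and early stopping, a detection/classification scorer with
    overlap analysis, and a deterministic synthetic-data generator for
    self-contained experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
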
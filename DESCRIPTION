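Package: plantchem
Title: Rule-Based Extraction of Plant-Chemical Relationships from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and mining a corpus of plant-chemical
    containment relationships from biomedical abstracts. Provides
    dictionary-based named entity recognition for plant and chemical
    mentions, sentence splitting and co-occurrence filtering, expansion of
    sentences into (plant, chemical) corpus units, readers and writers for
    the BioC XML interchange format and a tab-separated annotation-sheet
    layout, a typed-dependency data model with a CoNLL-style fixture
    reader, a rule-based relation classifier built on six families of
    Stanford-typed-dependency patterns with curated trigger lexicons, and
    the evaluation statistics used for such corpora (precision/recall/F1,
    simple percent agreement, Cohen's kappa). A template-driven synthetic
    corpus generator with gold dependency parses makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
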
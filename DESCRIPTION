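Package: embaudit
Title: Bias Audits of Word Embeddings for Mental-Health Terminology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing demographic bias in pre-trained word
    embeddings, with a focus on psychiatric and mental-health vocabulary.
    Reads GloVe text and word2vec binary embedding files, manages
    demographic and DSM-5-derived diagnosis lexicons with case-variant
    resolution, runs 3CosAdd analogy probes and lexicon-restricted
    nearest-neighbour audits, places terms along opposing-pole semantic
    axes (for example safe versus dangerous), compares rankings across
    embedding dimensionalities with pair-counted rank correlation, and
    generates synthetic embedding spaces with planted group-to-diagnosis
    bias so every stage is testable end to end without large downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
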
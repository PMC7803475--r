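Package: stsfuse
Title: Multi-Level Representation Fusion for Clinical Semantic Textual
    Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Regression modelling of clinical semantic textual similarity:
    scores pairs of clinical text snippets on the 0-5 similarity scale by
    fusing three representations of the pair -- a sentence-level encoding
    from a transformer pair encoder, a character-level convolutional
    encoding that is robust to out-of-vocabulary tokens, and entity-level
    encodings built either from clinical entity-type label sequences
    (siamese convolutional encoder) or from translation-based knowledge
    graph embeddings of the entities mentioned.  Includes a dictionary
    entity tagger over the nine standard clinical mention types, a TransE
    trainer for knowledge-graph triples, Pearson-correlation evaluation
    with fivefold cross-validation and a component ablation runner, and a
    synthetic corpus generator producing graded-similarity snippet pairs,
    entity lexica and toy knowledge graphs for fully self-contained
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
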
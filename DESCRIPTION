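Package: cpie
Title: Chemical-Protein Interaction Extraction with Contextual Embeddings and Multihead Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for sentence-level chemical-protein
    interaction (CPI) extraction from ChemProt-format corpora. Parses the
    three-file TSV corpus dialect (abstracts, entity mentions, relation
    annotations), generates labeled within-sentence (chemical, gene)
    candidate instances, and classifies them into the five evaluated CPR
    relation classes plus a negative class. The classifier combines
    per-token contextual representations from a small trainable
    bidirectional language model (mixed ELMo-style across layers) with
    position and part-of-speech embeddings, a bidirectional LSTM encoder,
    multihead scaled dot-product self-attention, attention pooling and a
    softmax output layer, all implemented with explicit forward and
    backward passes. Includes micro-averaged multiclass evaluation,
    attention-keyword reporting, and a synthetic ChemProt-format corpus
    generator with controllable difficulty so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
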
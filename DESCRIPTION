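Package: bioner
Title: Biomedical Named Entity Recognition with Character-Level
    Language-Model Embeddings and a BiLSTM-CRF Tagger
Version: 0.1.0
Authors@R:
    person("bioner", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for mention-level biomedical named
    entity recognition. Contextual token embeddings are extracted from
    forward and backward character-level recurrent language models and
    stacked with subword-hashed word embeddings; tagging is performed by a
    bidirectional LSTM encoder with an exact linear-chain conditional
    random field (forward-algorithm partition, Viterbi decoding). Distinct
    models are trained per entity type on the union of several corpora,
    with a pretrain-then-finetune protocol for in-corpus adaptation.
    Includes CoNLL column-format corpus input/output with pluggable
    segmentation, mention-level evaluation under an exact protocol with
    character-offset tolerance and a lenient any-overlap protocol, a
    seeded generator of synthetic annotated corpora with controllable
    annotation-convention divergence, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
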
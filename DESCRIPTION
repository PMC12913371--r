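Package: nestNER
Title: Nested Biomedical Named Entity Recognition with Structured Span
    Representations and Constraint-Guided Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A span-based framework for nested named entity recognition in
    biomedical (immunology) text. Candidate token spans are enumerated up to a
    maximum width, represented by multi-channel gated aggregation of token
    encodings with length embeddings, refined by structural attention over a
    span graph and span-level self-attention, and classified into a typed
    label set. A constraint-guided global decoder refines pruned candidates by
    graph message passing and ontology-aware sibling filtering, then selects a
    structurally consistent span subset by exhaustive enumeration or beam
    search under overlap, type-compatibility and nesting-prior terms. Includes
    readers and writers for PubTator, BRAT standoff and CoNLL corpora, a
    seeded synthetic nested-entity corpus generator, training objectives with
    prototype (center) and margin contrastive regularization, span-level
    exact-match evaluation, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'autodiff.R'
    'schema.R'
    'corpus.R'
    'bioes.R'
    'evaluate.R'
    'encoder-config.R'
    'encoder.R'
    'decoder.R'
    'losses.R'
    'train.R'
    'synthetic.R'
    'cli.R'
    'tokenize.R'
    'io-brat.R'
    'io-conll.R'
    'io-json.R'
    'io-pubtator.R'
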
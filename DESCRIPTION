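Package: mlner
Title: Multi-Level Transformer Representation Fusion for Clinical
    Named-Entity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Character-level named-entity recognition for clinical text
    with a transformer encoder whose intermediate layer states are fused
    per token by multi-head scaled dot-product attention over layers.
    Includes a synthetic annotated-corpus generator with CoNLL-style
    column file I/O, BIO tag encoding and decoding with repair policies,
    a small trainable encoder exposing every layer's hidden states,
    four layer-assembling strategies (multi-head fusion, concatenation,
    sum-average, last layer), an AdamW training loop with validation
    model selection, strict entity-level precision/recall/F1 with a
    brute-force oracle twin, and experiment harnesses for assembling
    method comparison, layer-subset ablation, and dataset-size curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
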
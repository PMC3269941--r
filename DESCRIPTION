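Package: genenorm
Title: Cross-Species Full-Text Gene Normalization by Soft Tagging of
    Overlapping Gene Mention Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A full-text gene normalization pipeline built around soft
    tagging: a linear-chain conditional random field gene-mention tagger with
    exact n-best Viterbi decoding in both parsing directions emits sets of
    overlapping mention variants; a logistic-regression evaluator assigns each
    variant a confidence score; heuristic rules designate a taxonomy
    identifier per variant; and a rule-normalized gene-name dictionary index
    with regular-expression post-filtering resolves variants to gene database
    identifiers. Includes abbreviation-definition filtering, synthetic corpus
    and dictionary generators for training and testing, and precision, recall,
    F-score and threshold average precision (TAP-k) evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
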
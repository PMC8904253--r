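Package: neurolex
Title: Lagged Encoding and Decoding of Word-Aligned Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery linking word embeddings to word-aligned
    intracranial neural activity: high-gamma broadband power preprocessing
    with an acausal-leak audit, lagged cross-validated linear encoding
    models, phase-randomization max-statistic permutation tests with FDR
    control, paired and bootstrap-shift model comparisons, entropy and
    cross-entropy (confidence/surprise) coupling, contextual-embedding
    manipulations (type averaging, occurrence scrambling, non-match
    assignment, context concatenation with PCA), and embedding-space
    decoding with a feed-forward regressor evaluated by frequency-weighted
    ROC-AUC. Ships a synthetic-data generator with known ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
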
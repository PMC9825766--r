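Package: pchicnet
Title: Multi-Modal Deep Learning for Promoter-Centered Chromatin Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting tissue-specific promoter-enhancer and
    promoter-promoter chromatin interactions from promoter-capture Hi-C
    summaries. Builds labeled datasets with FDR-based labeling and GC-matched
    negative sampling, extracts multi-modal features (one-hot anchor sequence,
    windowed epigenetic coverage, anchor distance, and optional conservation
    and DNA-shape tracks), trains a densely connected convolutional classifier
    with dilated convolutions under base, multi-task (shared/private) and
    transfer-learning paradigms, and evaluates models with repeated-split
    AUC/AUPRC experiments, rank aggregation and rank-sum comparisons. Includes
    a synthetic-study generator producing every input format the pipeline
    consumes so the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
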
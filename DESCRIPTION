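Package: tensorATM
Title: Annotated Transcriptional Modules from Literature Tensors by
    Non-Negative PARAFAC Factorization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a sparse 3-mode term x gene x transcription-factor
    tensor from gene-TF pairs that share literature citations, decomposes
    it by non-negative PARAFAC (CP) factorization with multiplicative
    alternating updates, and extracts Annotated Transcriptional Modules
    (ATMs): entropy-thresholded sets of significant terms, genes, and TFs
    from each rank-1 component. Includes hypergeometric gene-set
    enrichment, ranking AUC, precision against gold standards with
    matched random controls, Jaccard redundancy and diversity summaries,
    guilt-by-association and term-mapping category prediction, and a
    seeded synthetic-corpus generator with planted term-gene-TF blocks
    for offline end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
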
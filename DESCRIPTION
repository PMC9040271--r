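Package: markstate
Title: Predicting Gene Transcriptional State from Histone-Modification Peak Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretable pipeline that predicts binary gene
    transcriptional state (ON/OFF) from histone-modification ChIP-seq peak
    calls. Peak tracks in the ENCODE BED dialects (narrowPeak, broadPeak,
    gappedPeak) are reduced to per-gene, per-mark max-enrichment features
    over symmetric windows around each TSS; a logistic regression
    classifier is fitted with per-mark peak-format selection on validation
    AUROC; fitted models are interpreted through gene-wise regulative
    patterns (weighted input vectors) with Wald significance masking; and
    patterns are matched against ChromHMM-style emission vectors to rank
    chromatin states by mean predicted activation. A synthetic fixture
    generator with planted ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
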
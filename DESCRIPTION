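Package: somaticFDR
Title: Replicate-Derived False Discovery Rates for Somatic Mutation Calls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assigns a per-mutation confidence value, an empirical false
    discovery rate (FDR), to somatic single-nucleotide variant calls from
    tumor/normal next-generation sequencing experiments. The empirical null
    is a "same versus same" comparison of replicate profiles of the same
    sample, in which every call is by construction a false positive. The
    multi-dimensional per-call quality properties emitted by a caller are
    fused into a single generalized quality score Q by random-forest
    regression on a dominance-ordered intermediate FDR, and call counts are
    normalized by the common coverage of each comparison. Per-mutation FDRs
    support prioritization, threshold selection, and label-free benchmarking
    of callers, protocols and replicate designs through estimated ROC curves
    and AUC statistics. Includes a synthetic call-set generator with known
    labels for end-to-end validation, and a pipeline driver with a thin
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: SomaticMutation, VariantDetection, Sequencing, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
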
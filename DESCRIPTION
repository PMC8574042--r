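Package: enhancerRules
Title: Interpretable Fuzzy-Rule Enhancer Prediction from Histone Modification Signals
Version: 0.1.0
Authors@R:
    person("Regulatory", "Genomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns human-readable IF/THEN rules that map binned histone
    modification signals to enhancer probability using interval type-2
    fuzzy logic and a constrained evolutionary search. Provides genome
    tiling and signal ingestion, reporter-assay label processing, rule
    induction with expert-rule injection, probability thresholded region
    calling with gap-limited merging, promoter-contact and expression
    linkage, bidirectional nascent-transcription scoring, region-anchored
    signal profiles and enrichment statistics, plus a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
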
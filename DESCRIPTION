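Package: telodisjoin
Title: Calibrated ChIP, Hi-C Telomere Aggregation and Sister-Telomere
    Disjunction Scoring for Fission-Yeast-Like Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying condensin-dependent
    sister-telomere disjunction in fission-yeast-like genomes.  Implements
    spike-in calibrated ChIP quantification (per-base calibrated IP/Total
    ratio tracks, qPCR-style normalization, metagene profiles), Hi-C
    contact-matrix processing (square-root vanilla-coverage normalization,
    observed/expected, distance-decay curves, differential log2 maps, and
    chromosome-end aggregate analysis with rank quantization and
    Mann-Whitney-Wilcoxon comparison), and mitotic foci analytics
    (resolution-limited focus counting, spindle-length staging, and
    disjunction/non-disjunction scoring).  Ships synthetic-data generators
    with planted ground truth for all three assays, plus an end-to-end
    scenario runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    optparse,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
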
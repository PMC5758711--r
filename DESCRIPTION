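Package: emtarget
Title: Integration of Chromatin Binding with Inducible EMT Expression Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor binding regions from ChIP-seq with
    knockdown-reversibility microarray expression calls to classify direct and
    indirect targets of a chromatin regulator during epithelial-to-mesenchymal
    transition (EMT). Provides probe-level differential-expression and
    knockdown-sensitivity calling, peak-to-TSS annotation with signed distances,
    genomic-feature and chromatin-state labelling, distance-binned gene
    proportions and TSS metaprofiles, two-factor co-binding detection with
    standardized-width tag-count correlation, Fisher/hypergeometric enrichment
    statistics, peptide-array phospho-hit calling, fluorescence-intensity and
    pixel-colocalization quantification, and a synthetic-data generator with
    planted, recorded ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
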
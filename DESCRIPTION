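Package: cfChIPquant
Title: Quantification and Expression Concordance for Targeted Cell-Free ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies H3K36me3 (cf)ChIP-seq signal on targeted capture panels
    and relates it to gene expression. Implements coverage-factor based
    per-gene enrichment for ChIP samples, healthy-donor background-subtracted
    enrichment for plasma cfChIP samples, active/inactive gene classification
    with ROC analysis, differential-expression versus differential-enrichment
    agreement statistics, and paired mutational-allele-fraction comparisons
    between input and cfChIP compartments. Ships a seedable synthetic-data
    generator emulating panel counts, TPM matrices, hematopoietic background
    and allele-specific variant depths, so the whole pipeline is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    rtracklayer,
    pROC,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
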
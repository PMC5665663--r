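Package: panelcnv
Title: Whole-Exon Copy Number Variant Detection from Targeted Panel Coverage
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Depth-of-coverage detection of whole-exon copy number variants
    (CNVs) on high-coverage targeted sequencing panels, as used in molecular
    diagnosis of familial hypercholesterolemia (LDLR). Implements matched
    reference control selection by coverage similarity, library-size and
    GC-content normalization, per-target ratio and z-score metrics, Bayesian
    copy-number state assignment with variant-allele-fraction evidence,
    segmentation of contiguous targets into CNV events, and ratio/z-score
    filtration. Includes an MLPA-style probe ratio comparator, diagnostic
    concordance statistics (2x2 contingency, sensitivity, specificity,
    chi-square), and a synthetic cohort generator with implanted CNVs so the
    full calling workflow can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
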
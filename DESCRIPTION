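Package: sepeaks
Title: Super-Enhancer Calling and Differential Chromatin Accessibility
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for regulatory-genomics analysis of ATAC-seq and
    CUT&RUN peak data: replicate-consensus peak sets, differential
    accessibility threshold filtering, promoter/enhancer classification
    from histone-mark co-occurrence (H3K4me3, H3K4me1, H3K27ac),
    ROSE-style super-enhancer calling by stitching and a slope-one
    tangent cutoff on the ranked signal curve, nearest-TSS annotation,
    hypergeometric overlap enrichment, and binned signal metaprofiles.
    Includes a seeded synthetic-genome generator with planted ground
    truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    data.table,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
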
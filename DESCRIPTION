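Package: ChIPLatent
Title: Latent Epigenomic Factors from Binned ChIP-seq Peak Maps for
    Non-Coding Variant Interpretation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@chiplatent.org",
           role = c("aut", "cre"))
Description: Builds binned feature matrices ("ChIP-maps") from ChIP-seq peak
    files, removes technical batch effects by surrogate-variable regression
    while protecting covariate-labelled biological signal, discovers latent
    epigenomic factors by singular value decomposition with contribution and
    squared-cosine scoring, and maps user-supplied genomic loci (for example
    GWAS SNPs) to ranked, function-annotated latent factors. Includes
    exporters for GREAT enrichment queries, parsers for GREAT result tables,
    a GWAS-catalog coverage summary, a rank-robustness analysis, and a
    synthetic-corpus generator with planted factor structure for hermetic
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    sva
Config/testthat/edition: 3
biocViews: Epigenetics, ChIPSeq, BatchEffect, DimensionReduction,
    FunctionalGenomics, GenomeAnnotation
RoxygenNote: 7.3.3
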
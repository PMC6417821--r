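# Shared fixtures.  The default synthetic corpus and its full pipeline run
# are built once per session and reused across test files.

.fixtureCache <- new.env(parent = emptyenv())

# BED-coordinate bin label, matching the package's column labels.
binLab <- function(gr) {
    paste0(as.character(GenomicRanges::seqnames(gr)), ":",
           GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}

# Write a small BED file from a data.frame-like list of vectors.
writeBedFixture <- function(path, chrom, start, end, name = NULL,
                            score = NULL) {
    n <- length(chrom)
    if (is.null(name)) name <- paste0("p", seq_len(n))
    if (is.null(score)) score <- rep(10, n)
    write.table(data.frame(chrom, start, end, name, score), path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
}

# Random peaks GRanges on a small genome.
randomPeaks <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000,
                        maxWidth = 800) {
    start0 <- sample.int(maxPos - maxWidth, n, replace = TRUE) - 1L
    gr <- GenomicRanges::GRanges(
        sample(chroms, n, replace = TRUE),
        IRanges::IRanges(start0 + 1L, start0 + sample.int(maxWidth, n,
                                                          replace = TRUE)))
    S4Vectors::mcols(gr)$score <- round(runif(n, 5, 30), 3)
    S4Vectors::mcols(gr)$trackId <- "t"
    gr
}

# Default synthetic corpus realised on disk (cached).
syntheticCorpusFixture <- function() {
    if (!is.null(.fixtureCache$corpus)) return(.fixtureCache$corpus)
    design <- ChIPLatent::syntheticDesign()
    dir <- file.path(tempdir(), "chiplatent-corpus")
    corp <- ChIPLatent::generateCorpus(design, dir)
    .fixtureCache$corpus <- corp
    corp
}

# Full pipeline run on the default synthetic corpus (cached):
# ChIP-map -> transform -> SVA -> protected regression -> SVD.
pipelineFixture <- function() {
    if (!is.null(.fixtureCache$pipeline)) return(.fixtureCache$pipeline)
    corp <- syntheticCorpusFixture()
    cm <- ChIPLatent::buildChIPMapFromDir(
        corp$peaksDir, corp$chromSizesPath, corp$metadataPath,
        mode = "high_specificity")
    tm <- ChIPLatent::transformMap(cm)
    svs <- ChIPLatent::estimateSurrogateVariables(tm, nPermutations = 50,
                                                  sigLevel = 0.05, seed = 7)
    md <- ChIPLatent::readTrackMetadata(corp$metadataPath)
    # labelling threshold appropriate for a 24-track cohort
    svs <- ChIPLatent::associateSVs(svs, md, alphaAssoc = 1e-10)
    nm <- ChIPLatent::regressOutSVs(tm, svs, "antibody")
    model <- ChIPLatent::decomposeMap(nm)
    truth <- list(
        factors = read.table(corp$truthPaths[1], header = TRUE, sep = "\t"),
        tracks = read.table(corp$truthPaths[2], header = TRUE, sep = "\t"),
        bins = read.table(corp$truthPaths[3], header = TRUE, sep = "\t"))
    out <- list(corp = corp, design = corp$design, cm = cm, tm = tm,
                svs = svs, nm = nm, model = model, truth = truth,
                metadata = md)
    .fixtureCache$pipeline <- out
    out
}

# 0/1 indicator of a planted factor's bin support over the model's bins.
plantedBinIndicator <- function(fix, factorName) {
    tb <- fix$truth$bins
    labs <- paste0(tb$chrom, ":", tb$start, "-", tb$end)
    as.numeric(rownames(ChIPLatent::binLoadings(fix$model)) %in%
               labs[tb$name == factorName])
}
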
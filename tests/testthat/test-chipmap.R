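# Featurization: BED parsing, binning, intersection, ChIP-map assembly.

test_that("readPeakBed parses BED5 records in file order", {
    p <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t600\tp1\t7.0",
                 "chr1\t1500\t1700\tp2\t9.0",
                 "chr2\t0\t400\tp3\t5.3"), p)
    gr <- readPeakBed(p, "trackA")
    expect_length(gr, 3)
    expect_equal(S4Vectors::mcols(gr)$score, c(7.0, 9.0, 5.3))
    expect_equal(GenomicRanges::start(gr), c(101L, 1501L, 1L))
    expect_equal(GenomicRanges::end(gr), c(600L, 1700L, 400L))
    expect_equal(unique(S4Vectors::mcols(gr)$trackId), "trackA")
})

test_that("readPeakBed handles empty files and normalises chrom names", {
    p <- withr::local_tempfile(fileext = ".bed")
    file.create(p)
    expect_length(readPeakBed(p, "t"), 0)

    writeLines("1\t10\t20\tp\t6", p)
    gr <- readPeakBed(p, "t")
    expect_equal(as.character(GenomicRanges::seqnames(gr)), "chr1")
})

test_that("readPeakBed rejects malformed lines with a line diagnostic", {
    p <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t600\t100\tbad\t7.0", p)
    expect_error(readPeakBed(p, "t"), "line 1.*start >= end")

    writeLines(c("chr1\t1\t5\tok\t6", "chr1\t1.5\t5\tbad\t6"), p)
    expect_error(readPeakBed(p, "t"), "line 2.*non-integer")

    writeLines("chr1\t1\t5\tshort", p)
    expect_error(readPeakBed(p, "t"), "line 1.*BED5")

    writeLines("chr1\t1\t5\tneg\t-2", p)
    expect_error(readPeakBed(p, "t"), "negative score")
})

test_that("filterTopPeaks keeps the strongest peaks, ties by genome order", {
    gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(1, 101, 201, 301), width = 50))
    S4Vectors::mcols(gr)$score <- c(5, 9, 7, 8)
    expect_length(filterTopPeaks(gr, 25000), 4)  # fewer than nTop: all kept
    top2 <- filterTopPeaks(gr, 2)
    expect_setequal(S4Vectors::mcols(top2)$score, c(9, 8))

    ties <- GenomicRanges::GRanges(c("chr2", "chr1", "chr1"),
             IRanges::IRanges(c(500, 900, 100), width = 10))
    S4Vectors::mcols(ties)$score <- c(7, 7, 7)
    kept <- filterTopPeaks(ties, 2)
    expect_equal(as.character(GenomicRanges::seqnames(kept)),
                 c("chr1", "chr1"))
    expect_setequal(GenomicRanges::start(kept), c(100, 900))
})

test_that("binGenome tiles chromosomes with a trailing partial bin", {
    bins <- binGenome(c(chr1 = 2500), 1000)
    expect_length(bins, 3)
    expect_equal(GenomicRanges::start(bins), c(1L, 1001L, 2001L))
    expect_equal(GenomicRanges::end(bins), c(1000L, 2000L, 2500L))
    expect_equal(S4Vectors::mcols(bins)$binIndex, 1:3)

    expect_length(binGenome(c(chr1 = 1000), 1000), 1)  # exact tiling
    expect_error(binGenome(c(chr1 = 1000), 0), "binSize")
    expect_error(binGenome(c(chr1 = 0), 1000), "lengths")

    two <- binGenome(c(chr1 = 1500, chr2 = 800), 1000)
    expect_equal(as.character(GenomicRanges::seqnames(two)),
                 c("chr1", "chr1", "chr2"))
    expect_equal(S4Vectors::mcols(two)$binIndex, 1:3)
})

test_that("intersectPeaksBins follows half-open BED semantics", {
    bins <- binGenome(c(chr1 = 2000), 1000)
    peak <- function(s0, e0, score = 6) {
        gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1, e0))
        S4Vectors::mcols(gr)$score <- score
        gr
    }
    expect_equal(intersectPeaksBins(peak(100, 600), bins)$binIndex, 1L)
    span <- intersectPeaksBins(peak(900, 1100), bins)
    expect_equal(span$binIndex, c(1L, 2L))
    expect_equal(span$score, c(6, 6))
    # peak [1000,1001) starts where bin 1 ends: no overlap with bin 1
    edge <- intersectPeaksBins(peak(1000, 1001), bins)
    expect_equal(edge$binIndex, 2L)
})

test_that("peaks on chromosomes absent from the bins are tallied, not errors", {
    bins <- binGenome(c(chr1 = 2000), 1000)
    gr <- GenomicRanges::GRanges(c("chr1", "chr9"),
                                 IRanges::IRanges(c(1, 1), width = 10))
    S4Vectors::mcols(gr)$score <- c(6, 7)
    ov <- intersectPeaksBins(gr, bins)
    expect_equal(nrow(ov), 1L)
    expect_equal(attr(ov, "skippedPeaks"), 1L)
})

test_that("intersection agrees with a brute-force overlap oracle", {
    set.seed(42)
    bins <- binGenome(c(chr1 = 10000, chr2 = 10000), 1000)
    peaks <- randomPeaks(200)
    got <- intersectPeaksBins(peaks, bins)
    got <- got[order(got$peak, got$binIndex), ]
    # O(peaks x bins) check on half-open intervals
    oracle <- do.call(rbind, lapply(seq_along(peaks), function(i) {
        p <- peaks[i]
        hit <- which(
            as.character(GenomicRanges::seqnames(bins)) ==
                as.character(GenomicRanges::seqnames(p)) &
            GenomicRanges::start(bins) <= GenomicRanges::end(p) &
            GenomicRanges::end(bins) >= GenomicRanges::start(p))
        if (!length(hit)) return(NULL)
        data.frame(binIndex = hit,
                   score = S4Vectors::mcols(p)$score, peak = i)
    }))
    oracle <- oracle[order(oracle$peak, oracle$binIndex), ]
    expect_equal(got$binIndex, oracle$binIndex)
    expect_equal(got$score, oracle$score)
})

test_that("buildChIPMap aggregates scores per bin and drops empties", {
    bins <- binGenome(c(chr1 = 10000), 1000)
    mk <- function(s0, e0, score) {
        gr <- GenomicRanges::GRanges("chr1",
                IRanges::IRanges(s0 + 1, e0))
        S4Vectors::mcols(gr)$score <- score
        gr
    }
    # single peak in bin 4 of 10 -> 1 x 1 matrix, that bin retained
    one <- buildChIPMap(list(t1 = mk(3000, 3500, 6)), bins)
    expect_equal(dim(chipValues(one)), c(1L, 1L))
    expect_equal(S4Vectors::mcols(binRanges(one))$binIndex, 4L)

    # two tracks, same bin, same score
    two <- buildChIPMap(list(t1 = mk(0, 500, 6), t2 = mk(0, 500, 6)), bins)
    expect_equal(unname(chipValues(two)), matrix(c(6, 6), ncol = 1))

    # two peaks of one track in one bin: sum vs max aggregation
    both <- suppressWarnings(c(mk(0, 400, 6), mk(400, 900, 8)))
    expect_equal(unname(chipValues(buildChIPMap(list(t = both), bins))[1, 1]),
                 14)
    expect_equal(unname(chipValues(buildChIPMap(list(t = both), bins,
                                                aggregate = "max"))[1, 1]),
                 8)

    # empty tracks are dropped; all-empty errors
    e <- GenomicRanges::GRanges()
    S4Vectors::mcols(e)$score <- numeric(0)
    cm <- buildChIPMap(list(t1 = mk(0, 500, 6), t2 = e), bins)
    expect_equal(nTracks(cm), 1L)
    expect_error(buildChIPMap(list(t1 = e), bins), "all tracks are empty")
})

test_that("high-specificity mode filters per-track top peaks first", {
    bins <- binGenome(c(chr1 = 10000), 1000)
    gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(seq(1, 9001, by = 1000), width = 100))
    S4Vectors::mcols(gr)$score <- 5:14
    spec <- buildChIPMap(list(t = gr), bins, mode = "high_specificity",
                         nTop = 3)
    cov <- buildChIPMap(list(t = gr), bins, mode = "high_coverage")
    expect_equal(nBins(spec), 3L)
    expect_equal(nBins(cov), 10L)
    # high-coverage column set contains the high-specificity column set
    expect_true(all(binLab(binRanges(spec)) %in%
                    binLab(binRanges(cov))))
    expect_setequal(unname(chipValues(spec)[1, ]), c(12, 13, 14))
})

test_that("ChIP-map columns are exactly the bins hit by at least one peak", {
    set.seed(11)
    bins <- binGenome(c(chr1 = 10000, chr2 = 10000), 1000)
    tracks <- list(t1 = randomPeaks(30), t2 = randomPeaks(25))
    cm <- buildChIPMap(tracks, bins, mode = "high_coverage")
    expected <- sort(unique(unlist(lapply(tracks, function(p)
        intersectPeaksBins(p, bins)$binIndex))))
    expect_equal(S4Vectors::mcols(binRanges(cm))$binIndex, expected)
    expect_true(all(chipValues(cm) >= 0))
    expect_true(all(colSums(chipValues(cm) != 0) >= 1))
})

test_that("ChIP-map write/read round trip is bit-exact", {
    set.seed(3)
    bins <- binGenome(c(chr1 = 10000, chr2 = 5000), 1000)
    tracks <- list(a = randomPeaks(40), b = randomPeaks(35),
                   c = randomPeaks(20))
    meta <- data.frame(trackId = c("a", "b", "c"),
                       antibody = c("H3K4me3", NA, "CTCF"))
    cm <- buildChIPMap(tracks, bins, mode = "high_coverage",
                       trackMetadata = meta)
    # perturb a value to a full-precision double
    prefix <- file.path(withr::local_tempdir(), "map")
    writeChIPMap(cm, prefix)
    back <- readChIPMap(prefix)
    expect_identical(chipValues(back), chipValues(cm))
    expect_identical(GenomicRanges::start(binRanges(back)),
                     GenomicRanges::start(binRanges(cm)))
    expect_identical(as.character(trackData(back)$trackId),
                     as.character(trackData(cm)$trackId))
    expect_identical(chipMode(back), chipMode(cm))
    expect_identical(trackData(back)$antibody, trackData(cm)$antibody)
})

test_that("chromosome-sizes reader keeps autosomes and normalises names", {
    p <- withr::local_tempfile()
    writeLines(c("1\t1000", "chr2\t2000", "chrX\t500", "chrM\t100"), p)
    sz <- readChromSizes(p)
    expect_equal(names(sz), c("chr1", "chr2"))
    szAll <- readChromSizes(p, autosomesOnly = FALSE)
    expect_length(szAll, 4)
})

test_that("normalized maps and factor models serialise losslessly", {
    set.seed(71)
    bins <- binGenome(c(chr1 = 8000), 1000)
    w <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(paste0("t", 1:5), NULL))
    model <- decomposeMap(w, bins = bins,
                          tracks = S4Vectors::DataFrame(
                              trackId = paste0("t", 1:5)))
    dir <- withr::local_tempdir()
    writeLatentFactorModel(model, dir)
    back <- readLatentFactorModel(dir)
    expect_identical(trackLoadings(back), trackLoadings(model))
    expect_identical(binLoadings(back), binLoadings(model))
    expect_identical(singularValues(back), singularValues(model))
    expect_identical(GenomicRanges::start(binRanges(back)),
                     GenomicRanges::start(binRanges(model)))
    # a query against the reloaded reference gives identical scores
    qs <- querySet("chr1", pos = 2500)
    expect_identical(factorScores(rankFactors(back, qs)),
                     factorScores(rankFactors(model, qs)))

    nm <- methods::new("NormalizedMap", values = w, binRanges = bins,
                       trackData = S4Vectors::DataFrame(
                           trackId = paste0("t", 1:5)),
                       removedSVs = integer(0), keptSVs = integer(0),
                       svSet = methods::new("SurrogateVariableSet",
                           svMatrix = matrix(numeric(0), 5, 0),
                           singularValues = numeric(0),
                           permutationQuantiles = numeric(0),
                           associations = NULL, labels = list(),
                           protectedFlags = logical(0),
                           skippedCovariates = character(0),
                           alphaAssoc = NA_real_))
    prefix <- file.path(withr::local_tempdir(), "norm")
    writeNormalizedMap(nm, prefix)
    back2 <- readNormalizedMap(prefix)
    expect_identical(unname(chipValues(back2)), unname(chipValues(nm)))
})
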
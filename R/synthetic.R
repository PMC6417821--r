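# Synthetic corpus generation: peak BED files, track metadata, GWAS-catalog
# tables and GREAT-format result tables with planted latent structure, so
# that every pipeline stage can be tested hermetically against known truth.

#' Construct a synthetic corpus design
#'
#' The default design emulates the statistical structure the pipeline
#' assumes in a real peak corpus at desk scale: 24 lymphoblastoid-style
#' tracks over a 5,000-bin genome (two autosomes, 1 kbp bins), three
#' planted biological factors tied to a 4-level antibody covariate through
#' mutually orthogonal +/-1 contrast loadings, and one technical batch
#' factor tied to a balanced 2-level ancestry covariate.  Factor supports
#' are disjoint blocks of bins; amplitudes (peak-score deltas) are distinct
#' and ordered, and support sizes decrease with amplitude so the factors'
#' variance ordering matches the amplitude ordering.  Peak scores imitate a
#' q-value-thresholded corpus: every emitted peak has
#' \eqn{-\log_{10} q \ge 5} (q \eqn{\le 10^{-5}}).
#'
#' @param nTracks number of tracks; multiple of 4 (default 24).
#' @param chromSizes named chromosome lengths (default two chromosomes
#'   totalling 5 Mbp).
#' @param binSize bin width in bp (default 1000).
#' @param nFactors number of planted biological factors, at most 3
#'   (default 3).
#' @param nBatch number of technical batch factors, 0 or 1 (default 1).
#' @param deltas score amplitudes of the biological factors, distinct and
#'   decreasing (default 8, 6, 4).
#' @param batchDelta score amplitude of the batch factor (default 8).
#' @param supportSizes bins in each biological factor's support
#'   (default 300, 200, 120).
#' @param batchSupportSize bins in the batch support (default 150).
#' @param baseScore baseline peak score (default 20).
#' @param noiseSd Gaussian score noise (default 1).
#' @param missingRate fraction of metadata cells blanked (default 0.2).
#' @param scoreFloor minimum emitted score (default 5).
#' @param jitterPeaks if TRUE, peaks are jittered across bin boundaries to
#'   exercise intersection edge cases (default FALSE: peaks exactly at bin
#'   boundaries).
#' @param seed RNG seed (default 1).
#' @return a \code{\linkS4class{SyntheticDesign}}.
#' @export
syntheticDesign <- function(nTracks = 24,
                            chromSizes = c(chr1 = 3e6, chr2 = 2e6),
                            binSize = 1000, nFactors = 3, nBatch = 1,
                            deltas = c(8, 6, 4), batchDelta = 8,
                            supportSizes = c(300, 200, 120),
                            batchSupportSize = 150, baseScore = 20,
                            noiseSd = 1, missingRate = 0.2, scoreFloor = 5,
                            jitterPeaks = FALSE, seed = 1) {
    if (nTracks %% 4 != 0) stop("nTracks must be a multiple of 4")
    if (nFactors > 3) stop("at most 3 planted biological factors")
    nGenomeBins <- sum(ceiling(chromSizes / binSize))
    perGroup <- nTracks / 4
    antibodies <- rep(c("H3K4me1", "H3K4me3", "H3K27ac", "CTCF"),
                      each = perGroup)
    # ancestry balanced within each antibody group (orthogonal to contrasts)
    ancestry <- rep(rep(c("EUR", "AFR"), length.out = perGroup), times = 4)
    covariates <- data.frame(trackId = sprintf("track%02d", seq_len(nTracks)),
                             antibody = antibodies, ancestry = ancestry,
                             stringsAsFactors = FALSE)
    # mutually orthogonal +/-1 contrasts over the 4 antibody groups
    contrasts <- list(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
    groupIdx <- rep(1:4, each = perGroup)

    supportStarts <- c(101, 1201, 2301)
    planted <- lapply(seq_len(nFactors), function(f) {
        list(name = paste0("bio", f), covariate = "antibody",
             trackLoading = contrasts[[f]][groupIdx],
             bins = seq(supportStarts[f],
                        length.out = supportSizes[f]),
             delta = deltas[f])
    })
    batch <- if (nBatch >= 1) {
        list(list(name = "batch1", covariate = "ancestry",
                  trackLoading = ifelse(ancestry == "EUR", 1, -1),
                  bins = seq(3501, length.out = batchSupportSize),
                  delta = batchDelta))
    } else list()
    if (max(vapply(c(planted, batch), function(f) max(f$bins), numeric(1),
                   USE.NAMES = FALSE), 0) > nGenomeBins)
        stop("factor supports exceed the genome bin count")
    methods::new("SyntheticDesign", nTracks = as.integer(nTracks),
                 chromSizes = chromSizes, binSize = as.integer(binSize),
                 plantedFactors = planted, batchFactors = batch,
                 covariates = covariates, missingRate = missingRate,
                 noiseSd = noiseSd, baseScore = baseScore,
                 scoreFloor = scoreFloor, jitterPeaks = jitterPeaks,
                 seed = as.integer(seed))
}

#' Generate a synthetic peak corpus on disk
#'
#' Realises a design as per-track BED peak files plus a metadata TSV, a
#' chromosome-sizes TSV and truth tables recording every planted vector.
#' The signal model is
#' \eqn{score(i,j) = base + \delta_f \, u_f(i) + \epsilon} for bin \eqn{j}
#' in factor \eqn{f}'s support (Gaussian \eqn{\epsilon}); entries below the
#' score floor are censored (no peak), all other bins carry no peak.
#' Output is deterministic per seed (byte-identical files).
#'
#' @param design a \code{\linkS4class{SyntheticDesign}}.
#' @param dir output directory (created; BED files under
#'   \code{<dir>/peaks/}).
#' @return invisible list with the output paths and the realised raw score
#'   matrix (tracks x genome bins).
#' @export
generateCorpus <- function(design, dir) {
    stopifnot(methods::is(design, "SyntheticDesign"))
    peaksDir <- file.path(dir, "peaks")
    dir.create(peaksDir, recursive = TRUE, showWarnings = FALSE)
    nBinsG <- sum(ceiling(design@chromSizes / design@binSize))
    bins <- binGenome(design@chromSizes, design@binSize)

    out <- withSeed(design@seed, {
        x <- matrix(0, nrow = design@nTracks, ncol = nBinsG)
        for (f in c(design@plantedFactors, design@batchFactors)) {
            sig <- outer(design@baseScore + f$delta * f$trackLoading,
                         rep(1, length(f$bins)))
            sig <- sig + matrix(stats::rnorm(length(sig), 0, design@noiseSd),
                                nrow = nrow(sig))
            x[, f$bins] <- x[, f$bins] + sig
        }
        x[x < design@scoreFloor] <- 0

        # metadata with missing cells
        md <- design@covariates
        for (col in setdiff(names(md), "trackId")) {
            blank <- stats::runif(nrow(md)) < design@missingRate
            md[[col]][blank] <- NA
        }
        jitter <- if (design@jitterPeaks)
            sample(-499:499, design@nTracks, replace = TRUE) else
            rep(0L, design@nTracks)
        list(x = x, md = md, jitter = jitter)
    })
    x <- out$x

    chromEnds <- cumsum(ceiling(design@chromSizes / design@binSize))
    bedPaths <- character(design@nTracks)
    for (i in seq_len(design@nTracks)) {
        j <- which(x[i, ] > 0)
        path <- file.path(peaksDir,
                          paste0(design@covariates$trackId[i], ".bed"))
        bedPaths[i] <- path
        if (length(j) == 0L) {
            file.create(path)
            next
        }
        gr <- bins[j]
        start0 <- GenomicRanges::start(gr) - 1L + out$jitter[i]
        end0 <- GenomicRanges::end(gr) + out$jitter[i]
        # clamp jittered peaks to the chromosome
        start0 <- pmax(start0, 0L)
        bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = start0, end = end0,
                          name = sprintf("peak%05d", seq_along(j)),
                          score = formatExact(x[i, j]))
        utils::write.table(bed, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }

    metadataPath <- file.path(dir, "metadata.tsv")
    utils::write.table(out$md, metadataPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    chromPath <- file.path(dir, "chrom.sizes")
    utils::write.table(data.frame(names(design@chromSizes),
                                  format(design@chromSizes,
                                         scientific = FALSE, trim = TRUE)),
                       chromPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    # truth tables: factor summary, track loadings, bin supports
    facs <- c(design@plantedFactors, design@batchFactors)
    types <- c(rep("biological", length(design@plantedFactors)),
               rep("batch", length(design@batchFactors)))
    truthFactors <- data.frame(
        name = vapply(facs, `[[`, character(1), "name"),
        type = types,
        covariate = vapply(facs, `[[`, character(1), "covariate"),
        delta = vapply(facs, `[[`, numeric(1), "delta"),
        supportSize = vapply(facs, function(f) length(f$bins), integer(1)))
    tl <- vapply(facs, `[[`, numeric(design@nTracks), "trackLoading")
    colnames(tl) <- truthFactors$name
    truthTracks <- cbind(data.frame(trackId = design@covariates$trackId),
                         as.data.frame(tl))
    truthBins <- if (length(facs) == 0L)
        data.frame(name = character(0), chrom = character(0),
                   start = integer(0), end = integer(0),
                   binIndex = integer(0))
    else do.call(rbind, lapply(facs, function(f) {
        gr <- bins[f$bins]
        data.frame(name = f$name,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), binIndex = f$bins)
    }))
    truthPaths <- file.path(dir, c("truth_factors.tsv", "truth_tracks.tsv",
                                   "truth_bins.tsv"))
    utils::write.table(truthFactors, truthPaths[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truthTracks, truthPaths[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truthBins, truthPaths[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(peaksDir = peaksDir, bedPaths = bedPaths,
                   metadataPath = metadataPath, chromSizesPath = chromPath,
                   truthPaths = truthPaths, scores = x, design = design))
}

#' Generate query SNPs with known expected outcomes
#'
#' Places SNPs in the support bins of chosen planted factors (where their
#' expected top factor is known by construction) plus decoy SNPs in empty
#' genomic regions (expected unmapped).  Positions are 1-based bin
#' midpoints.
#'
#' @param design the \code{\linkS4class{SyntheticDesign}} used for the
#'   corpus.
#' @param nPerFactor SNPs per biological factor (default 5).
#' @param nDecoys decoy SNPs outside every support (default 3).
#' @return data.frame with columns snpId, chrom, pos (1-based),
#'   expectedFactor (planted factor name, NA for decoys), expectedOutcome
#'   (\code{"mapped"}/\code{"unmapped"}).
#' @export
generateQueryTruth <- function(design, nPerFactor = 5, nDecoys = 3) {
    bins <- binGenome(design@chromSizes, design@binSize)
    rows <- list()
    for (f in design@plantedFactors) {
        idx <- utils::head(f$bins, nPerFactor)
        gr <- bins[idx]
        rows[[f$name]] <- data.frame(
            snpId = sprintf("rs_%s_%02d", f$name, seq_along(idx)),
            chrom = as.character(GenomicRanges::seqnames(gr)),
            pos = GenomicRanges::start(gr) +
                floor(GenomicRanges::width(gr) / 2),
            expectedFactor = f$name, expectedOutcome = "mapped")
    }
    used <- sort(unique(unlist(lapply(
        c(design@plantedFactors, design@batchFactors), `[[`, "bins"))))
    free <- setdiff(seq_along(bins), used)
    idx <- free[seq_len(min(nDecoys, length(free)))]
    gr <- bins[idx]
    rows$decoys <- data.frame(
        snpId = sprintf("rs_decoy_%02d", seq_along(idx)),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr) + floor(GenomicRanges::width(gr) / 2),
        expectedFactor = NA_character_, expectedOutcome = "unmapped")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Generate mock GREAT result tables
#'
#' Writes syntactically valid GREAT-export TSVs with controlled term lists,
#' one file per (factor, ontology), named \code{factor<k>.<ontology>.tsv}.
#'
#' @param factorTerms named list (one entry per factor index) of data.frames
#'   with columns ontology, termId, termName, binomP, binomFdr, binomFold;
#'   if NULL, a small default HPO/GO term set is produced for
#'   \code{nFactors} factors.
#' @param dir output directory.
#' @param nFactors number of factors when \code{factorTerms} is NULL.
#' @return character vector of file paths, invisibly.
#' @export
generateGreatMock <- function(factorTerms = NULL, dir, nFactors = 3) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(factorTerms)) {
        defaults <- function(k) data.frame(
            ontology = c("HPO", "HPO", "GO"),
            termId = c("HP:0012140", "HP:0001888",
                       sprintf("GO:%07d", 6950 + k)),
            termName = c("Abnormality of cells of the lymphoid lineage",
                         "Lymphopenia", "response to stress"),
            binomP = c(1.1e-5, 1.4e-5, 2e-4) * k,
            binomFdr = c(2.7e-4, 2.8e-4, 5e-3) * k,
            binomFold = c(2.5, 2.2, 1.8))
        factorTerms <- stats::setNames(lapply(seq_len(nFactors), defaults),
                                       seq_len(nFactors))
    }
    paths <- character(0)
    for (k in names(factorTerms)) {
        terms <- factorTerms[[k]]
        if (nrow(terms) == 0L) {
            p <- file.path(dir, sprintf("factor%s.all.tsv", k))
            writeLines(paste(c("Ontology", "ID", "Desc", "BinomP",
                               "BinomFdrQ", "RegionFoldEnrich"),
                             collapse = "\t"), p)
            paths <- c(paths, p)
            next
        }
        for (ont in unique(terms$ontology)) {
            sub <- terms[terms$ontology == ont, , drop = FALSE]
            tab <- data.frame(Ontology = sub$ontology, ID = sub$termId,
                              Desc = sub$termName, BinomP = sub$binomP,
                              BinomFdrQ = sub$binomFdr,
                              RegionFoldEnrich = sub$binomFold)
            p <- file.path(dir, sprintf("factor%s.%s.tsv", k, tolower(ont)))
            utils::write.table(tab, p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            paths <- c(paths, p)
        }
    }
    invisible(paths)
}
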
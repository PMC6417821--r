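# Featurization: peak BED parsing, genome binning, peak-bin intersection and
# assembly of the ChIP-map feature matrix.

#' Read a ChIP-seq peak BED file
#'
#' Parses a BED5+ peak file whose score column holds the peak's
#' \eqn{-\log_{10}} FDR q-value.  Coordinates follow the BED convention
#' (0-based, half-open) and are converted to the 1-based closed convention of
#' \code{GRanges}; chromosome names are normalised to the \code{"chr"} prefix.
#'
#' @param path path to a tab-separated BED file with at least 5 columns
#'   (chrom, start, end, name, score).
#' @param trackId identifier of the source assay, attached to every peak.
#' @return \code{GRanges} with metadata columns \code{score} (numeric,
#'   \eqn{\ge 0}) and \code{trackId}, in file order.  An empty file yields a
#'   zero-length \code{GRanges} (the caller drops the track).
#' @details A malformed line (fewer than 5 fields, non-integer coordinates,
#'   \code{start >= end}, negative or non-numeric score) rejects the whole
#'   file with a diagnostic naming the offending line.
#' @export
readPeakBed <- function(path, trackId) {
    if (!file.exists(path)) stop("peak file does not exist: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!grepl("^(track|browser|#)", lines)]
    if (length(lines) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$score <- numeric(0)
        S4Vectors::mcols(gr)$trackId <- character(0)
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 5L)) {
        bad <- which(nf < 5L)[1]
        stop(sprintf("%s: line %d has %d fields; need >= 5 (BED5)",
                     path, bad, nf[bad]))
    }
    chrom <- vapply(fields, `[[`, character(1), 1L)
    startStr <- vapply(fields, `[[`, character(1), 2L)
    endStr <- vapply(fields, `[[`, character(1), 3L)
    scoreStr <- vapply(fields, `[[`, character(1), 5L)
    start <- suppressWarnings(as.integer(startStr))
    end <- suppressWarnings(as.integer(endStr))
    score <- suppressWarnings(as.numeric(scoreStr))
    badCoord <- which(is.na(start) | is.na(end) |
                      startStr != as.character(start) |
                      endStr != as.character(end))
    if (length(badCoord))
        stop(sprintf("%s: line %d has non-integer coordinates", path,
                     badCoord[1]))
    badIv <- which(start >= end)
    if (length(badIv))
        stop(sprintf("%s: line %d has start >= end (%d >= %d)", path,
                     badIv[1], start[badIv[1]], end[badIv[1]]))
    badScore <- which(is.na(score) | score < 0)
    if (length(badScore))
        stop(sprintf("%s: line %d has a non-numeric or negative score", path,
                     badScore[1]))
    gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                                 IRanges::IRanges(start + 1L, end))
    S4Vectors::mcols(gr)$score <- score
    S4Vectors::mcols(gr)$trackId <- as.character(trackId)
    gr
}

#' Keep the top-scoring peaks of a track
#'
#' Retains the \code{nTop} peaks with the largest \eqn{-\log_{10}} q-value;
#' the high-specificity reference keeps the top 25,000 peaks per track to
#' limit experimental-design confounding.  Ties at the cutoff are broken
#' deterministically by genome order (chrom, start).
#'
#' @param peaks \code{GRanges} of peaks with a \code{score} column.
#' @param nTop number of peaks to keep (default 25000).
#' @return \code{GRanges} of at most \code{nTop} peaks.
#' @export
filterTopPeaks <- function(peaks, nTop = 25000) {
    stopifnot(nTop >= 1)
    if (length(peaks) <= nTop) return(peaks)
    o <- order(-S4Vectors::mcols(peaks)$score,
               as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks), method = "radix")
    peaks[sort(o[seq_len(nTop)])]  # selected records, original order
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length (no header).
#' @param autosomesOnly drop sex chromosomes and non-canonical contigs
#'   (default TRUE; the reference maps are built on autosomes).
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path, autosomesOnly = TRUE) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    chrom <- normalizeChrom(tab$chrom)
    sizes <- stats::setNames(tab$length, chrom)
    if (autosomesOnly) sizes <- sizes[grepl("^chr[0-9]+$", names(sizes))]
    sizes
}

#' Tile the genome into fixed-size bins
#'
#' Produces half-open bins \eqn{[0,b), [b,2b), \dots} per chromosome (default
#' \eqn{b} = 1 kbp); a trailing partial bin covering the chromosome tail is
#' emitted.  Bin indices are assigned in the chromosome order of
#' \code{chromSizes}, then by coordinate.
#'
#' @param chromSizes named numeric vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 1000).
#' @return \code{GRanges} with metadata column \code{binIndex}.
#' @export
binGenome <- function(chromSizes, binSize = 1000) {
    if (binSize < 1) stop("binSize must be >= 1")
    if (length(chromSizes) == 0L) stop("chromSizes is empty")
    if (any(chromSizes < 1)) stop("chromosome lengths must be >= 1")
    chroms <- normalizeChrom(names(chromSizes))
    pieces <- lapply(seq_along(chromSizes), function(i) {
        len <- chromSizes[[i]]
        starts0 <- seq(0L, len - 1L, by = binSize)
        ends0 <- pmin(starts0 + binSize, len)
        GenomicRanges::GRanges(chroms[i],
                               IRanges::IRanges(starts0 + 1L, ends0))
    })
    bins <- suppressWarnings(do.call(c, pieces))
    S4Vectors::mcols(bins)$binIndex <- seq_along(bins)
    bins
}

#' Intersect peaks with genomic bins
#'
#' BED-intersect semantics on half-open intervals: every (peak, bin) pair
#' with at least 1 bp of overlap yields one (binIndex, score) row; a peak
#' spanning k bins yields k rows with the same score.  Peaks on chromosomes
#' absent from the bin set are silently skipped and counted in the
#' \code{"skippedPeaks"} attribute.
#'
#' @param peaks \code{GRanges} with a \code{score} column.
#' @param bins \code{GRanges} with a \code{binIndex} column (sorted,
#'   non-overlapping per chromosome).
#' @return data.frame with columns \code{binIndex}, \code{score},
#'   \code{peak} (index into \code{peaks}); attribute \code{skippedPeaks}
#'   holds the count of peaks on absent chromosomes.
#' @export
intersectPeaksBins <- function(peaks, bins) {
    binChroms <- GenomeInfoDb::seqlevels(bins)
    off <- !(as.character(GenomicRanges::seqnames(peaks)) %in% binChroms)
    nSkipped <- sum(off)
    hits <- GenomicRanges::findOverlaps(peaks[!off], bins, minoverlap = 1L)
    keptIdx <- which(!off)
    out <- data.frame(
        binIndex = S4Vectors::mcols(bins)$binIndex[S4Vectors::subjectHits(hits)],
        score = S4Vectors::mcols(peaks)$score[keptIdx[S4Vectors::queryHits(hits)]],
        peak = keptIdx[S4Vectors::queryHits(hits)])
    attr(out, "skippedPeaks") <- nSkipped
    out
}

#' Assemble the ChIP-map feature matrix
#'
#' Builds the tracks-by-bins matrix of aggregated \eqn{-\log_{10}} q-values.
#' In \code{high_specificity} mode each track is first reduced to its
#' \code{nTop} strongest peaks; \code{high_coverage} uses all peaks.  Scores
#' of a track's peak fragments falling in one bin are aggregated (sum by
#' default, max available).  Bins hit by no peak in any kept track are
#' removed (their original coordinates and genome-wide \code{binIndex} are
#' retained on the survivors); empty tracks are dropped.
#'
#' @param trackPeaks named list of peak \code{GRanges}, one per track.
#' @param bins genome bins from \code{\link{binGenome}}.
#' @param mode \code{"high_specificity"} or \code{"high_coverage"}.
#' @param nTop top-peak filter size for high-specificity mode (default 25000).
#' @param aggregate \code{"sum"} (default, accumulates evidence) or
#'   \code{"max"}.
#' @param trackMetadata optional data.frame of per-track covariates with a
#'   \code{trackId} column; merged into \code{colData}.
#' @return a \code{\linkS4class{ChIPMap}}.
#' @export
buildChIPMap <- function(trackPeaks, bins,
                         mode = c("high_specificity", "high_coverage"),
                         nTop = 25000, aggregate = c("sum", "max"),
                         trackMetadata = NULL) {
    mode <- match.arg(mode)
    aggregate <- match.arg(aggregate)
    if (length(trackPeaks) == 0L) stop("no tracks supplied")
    if (is.null(names(trackPeaks)))
        names(trackPeaks) <- paste0("track", seq_along(trackPeaks))
    nRaw <- vapply(trackPeaks, length, integer(1))
    keep <- nRaw > 0L
    if (!any(keep)) stop("all tracks are empty; cannot build a ChIP-map")
    trackPeaks <- trackPeaks[keep]
    nRaw <- nRaw[keep]
    if (mode == "high_specificity")
        trackPeaks <- lapply(trackPeaks, filterTopPeaks, nTop = nTop)
    nKept <- vapply(trackPeaks, length, integer(1))

    nSkipped <- 0L
    triplets <- lapply(seq_along(trackPeaks), function(i) {
        ov <- intersectPeaksBins(trackPeaks[[i]], bins)
        nSkipped <<- nSkipped + attr(ov, "skippedPeaks")
        if (nrow(ov) == 0L)
            return(data.frame(track = integer(0), binIndex = integer(0),
                              value = numeric(0)))
        agg <- if (aggregate == "sum") {
            rowsum(ov$score, ov$binIndex)
        } else {
            tapply(ov$score, ov$binIndex, max)
        }
        data.frame(track = i,
                   binIndex = as.integer(rownames(agg) %||% names(agg)),
                   value = as.numeric(agg))
    })
    trip <- do.call(rbind, triplets)
    if (nrow(trip) == 0L)
        stop("no peak overlaps any genomic bin; cannot build a ChIP-map")
    usedBins <- sort(unique(trip$binIndex))
    mat <- matrix(0, nrow = length(usedBins), ncol = length(trackPeaks),
                  dimnames = list(NULL, names(trackPeaks)))
    mat[cbind(match(trip$binIndex, usedBins), trip$track)] <- trip$value

    keptBins <- bins[match(usedBins, S4Vectors::mcols(bins)$binIndex)]
    cd <- S4Vectors::DataFrame(trackId = names(trackPeaks),
                               nPeaksRaw = as.integer(nRaw),
                               nPeaksKept = as.integer(nKept))
    if (!is.null(trackMetadata)) {
        m <- trackMetadata[match(names(trackPeaks), trackMetadata$trackId), ,
                           drop = FALSE]
        for (col in setdiff(names(m), "trackId")) cd[[col]] <- m[[col]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = mat), rowRanges = keptBins, colData = cd)
    obj <- methods::new("ChIPMap", se, mode = mode)
    S4Vectors::metadata(obj)$aggregate <- aggregate
    S4Vectors::metadata(obj)$nTop <- if (mode == "high_specificity") nTop else NA
    S4Vectors::metadata(obj)$skippedPeaks <- nSkipped
    obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a ChIP-map from a directory of peak BED files
#'
#' Convenience wrapper: reads every \code{*.bed} file in \code{peaksDir}
#' (track id = file name without extension), tiles the genome from a
#' chromosome-sizes file, and assembles the ChIP-map.
#'
#' @param peaksDir directory of BED5+ peak files.
#' @param chromSizesPath two-column chromosome-sizes TSV.
#' @param metadataPath optional track-metadata TSV (column \code{trackId}).
#' @param binSize bin width in bp.
#' @inheritParams buildChIPMap
#' @return a \code{\linkS4class{ChIPMap}}.
#' @export
buildChIPMapFromDir <- function(peaksDir, chromSizesPath, metadataPath = NULL,
                                binSize = 1000,
                                mode = c("high_specificity", "high_coverage"),
                                nTop = 25000, aggregate = c("sum", "max")) {
    files <- sort(list.files(peaksDir, pattern = "\\.bed$", full.names = TRUE))
    if (length(files) == 0L) stop("no .bed files in ", peaksDir)
    ids <- sub("\\.bed$", "", basename(files))
    peaks <- Map(readPeakBed, files, ids)
    names(peaks) <- ids
    bins <- binGenome(readChromSizes(chromSizesPath), binSize)
    meta <- if (!is.null(metadataPath)) readTrackMetadata(metadataPath)
    buildChIPMap(peaks, bins, mode = match.arg(mode), nTop = nTop,
                 aggregate = match.arg(aggregate), trackMetadata = meta)
}

#' Read a track-metadata table
#'
#' TSV with a \code{trackId} column plus arbitrary covariate columns; empty
#' cells are missing values.
#'
#' @param path path to the TSV.
#' @return data.frame with NA for missing cells.
#' @export
readTrackMetadata <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             na.strings = c("", "NA"))
    if (!"trackId" %in% names(tab))
        stop("metadata table must have a 'trackId' column")
    tab
}
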
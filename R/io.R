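# Plain-text serialisation of ChIP-maps: dense TSV, sparse triplet TSV,
# bins BED and track-metadata TSV, written under a common prefix.

#' Write a ChIP-map to disk
#'
#' Writes four plain-text files under \code{prefix}: a dense TSV
#' (\code{<prefix>.dense.tsv}; header row of \code{"chrom:start-end"} bin
#' labels, first column of track ids), a sparse triplet TSV
#' (\code{<prefix>.sparse.tsv}; track_id, bin_label, value), the surviving
#' bins as BED with their genome-wide bin index
#' (\code{<prefix>.bins.bed}) and the track table
#' (\code{<prefix>.tracks.tsv}).  Values are written with enough digits that
#' a read round trip is bit-exact.
#'
#' @param x a \code{\linkS4class{ChIPMap}}.
#' @param prefix output path prefix.
#' @return the four file paths, invisibly.
#' @export
writeChIPMap <- function(x, prefix) {
    stopifnot(methods::is(x, "ChIPMap"))
    vals <- chipValues(x)  # N x M
    densePath <- paste0(prefix, ".dense.tsv")
    sparsePath <- paste0(prefix, ".sparse.tsv")
    binsPath <- paste0(prefix, ".bins.bed")
    tracksPath <- paste0(prefix, ".tracks.tsv")

    labels <- colnames(vals)
    con <- file(densePath, "w")
    writeLines(paste(c("track_id", labels), collapse = "\t"), con)
    for (i in seq_len(nrow(vals)))
        writeLines(paste(c(rownames(vals)[i], formatExact(vals[i, ])),
                         collapse = "\t"), con)
    close(con)

    nz <- which(vals != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
    sp <- data.frame(track_id = rownames(vals)[nz[, 1]],
                     bin_label = labels[nz[, 2]],
                     value = formatExact(vals[nz]))
    utils::write.table(sp, sparsePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    gr <- binRanges(x)
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      binIndex = S4Vectors::mcols(gr)$binIndex)
    utils::write.table(bed, binsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)

    td <- as.data.frame(trackData(x))
    td$mode <- chipMode(x)
    utils::write.table(td, tracksPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(c(dense = densePath, sparse = sparsePath, bins = binsPath,
                tracks = tracksPath))
}

#' Read a ChIP-map written by \code{writeChIPMap}
#'
#' @param prefix the prefix passed to \code{\link{writeChIPMap}}.
#' @return a \code{\linkS4class{ChIPMap}} reproducing values, bin
#'   coordinates and track order bit-exactly.
#' @export
readChIPMap <- function(prefix) {
    densePath <- paste0(prefix, ".dense.tsv")
    binsPath <- paste0(prefix, ".bins.bed")
    tracksPath <- paste0(prefix, ".tracks.tsv")
    for (p in c(densePath, binsPath, tracksPath))
        if (!file.exists(p)) stop("missing ChIP-map component: ", p)

    lines <- readLines(densePath)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    trackIds <- vapply(body, `[[`, character(1), 1L)
    vals <- t(vapply(body, function(f) as.numeric(f[-1]),
                     numeric(length(header) - 1L)))
    if (length(header) == 2L) vals <- matrix(vals, ncol = 1L)
    rownames(vals) <- trackIds
    colnames(vals) <- header[-1]

    bed <- utils::read.table(binsPath, sep = "\t", header = FALSE,
                             col.names = c("chrom", "start", "end",
                                           "binIndex"))
    gr <- GenomicRanges::GRanges(bed$chrom,
                                 IRanges::IRanges(bed$start + 1L, bed$end))
    S4Vectors::mcols(gr)$binIndex <- bed$binIndex

    td <- utils::read.table(tracksPath, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            na.strings = "")
    mode <- td$mode[1]
    td <- td[match(trackIds, td$trackId), setdiff(names(td), "mode"),
             drop = FALSE]
    cd <- S4Vectors::DataFrame(td)
    cd$nPeaksRaw <- as.integer(cd$nPeaksRaw)
    cd$nPeaksKept <- as.integer(cd$nPeaksKept)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = t(vals)), rowRanges = gr, colData = cd)
    methods::new("ChIPMap", se, mode = mode)
}

#' Write / read a normalized ChIP-map
#'
#' Serialises the residual matrix together with its bins and track table
#' under a common prefix (\code{<prefix>.dense.tsv}, \code{<prefix>.bins.bed},
#' \code{<prefix>.tracks.tsv}), in the same dense format as
#' \code{\link{writeChIPMap}}.  SV bookkeeping is not persisted.
#'
#' @param x a \code{\linkS4class{NormalizedMap}}.
#' @param prefix output path prefix.
#' @return file paths (write) or a \code{NormalizedMap} (read), the latter
#'   with empty SV bookkeeping.
#' @export
writeNormalizedMap <- function(x, prefix) {
    vals <- chipValues(x)
    writeMatrixTsv(vals, paste0(prefix, ".dense.tsv"), rowLabel = "track_id")
    gr <- binRanges(x)
    utils::write.table(
        data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   S4Vectors::mcols(gr)$binIndex),
        paste0(prefix, ".bins.bed"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    utils::write.table(as.data.frame(trackData(x)),
                       paste0(prefix, ".tracks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    invisible(paste0(prefix, c(".dense.tsv", ".bins.bed", ".tracks.tsv")))
}

#' @rdname writeNormalizedMap
#' @export
readNormalizedMap <- function(prefix) {
    vals <- readMatrixTsv(paste0(prefix, ".dense.tsv"))
    bed <- utils::read.table(paste0(prefix, ".bins.bed"), sep = "\t")
    gr <- GenomicRanges::GRanges(bed[[1]],
                                 IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
    S4Vectors::mcols(gr)$binIndex <- bed[[4]]
    td <- utils::read.table(paste0(prefix, ".tracks.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE,
                            colClasses = "character", na.strings = "")
    methods::new("NormalizedMap", values = vals, binRanges = gr,
                 trackData = S4Vectors::DataFrame(td),
                 removedSVs = integer(0), keptSVs = integer(0),
                 svSet = methods::new("SurrogateVariableSet",
                     svMatrix = matrix(numeric(0), nrow(vals), 0),
                     singularValues = numeric(0),
                     permutationQuantiles = numeric(0), associations = NULL,
                     labels = list(), protectedFlags = logical(0),
                     skippedCovariates = character(0),
                     alphaAssoc = NA_real_))
}

#' Write / read a latent factor model directory
#'
#' Persists \eqn{U}, \eqn{D}, \eqn{V}, the bin coordinates and the track
#' table as plain TSV/BED files in \code{dir} — the reference layout the
#' query pipeline loads.
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param dir directory (created if needed).
#' @return the directory (write) or a \code{LatentFactorModel} (read).
#' @export
writeLatentFactorModel <- function(model, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeMatrixTsv(trackLoadings(model), file.path(dir, "U.tsv"),
                   rowLabel = "track_id")
    writeLines(formatExact(singularValues(model)), file.path(dir, "D.tsv"))
    writeMatrixTsv(binLoadings(model), file.path(dir, "V.tsv"),
                   rowLabel = "bin_label")
    gr <- binRanges(model)
    utils::write.table(
        data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   S4Vectors::mcols(gr)$binIndex %||% seq_along(gr)),
        file.path(dir, "bins.bed"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    utils::write.table(as.data.frame(trackData(model)),
                       file.path(dir, "tracks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    invisible(dir)
}

#' @rdname writeLatentFactorModel
#' @export
readLatentFactorModel <- function(dir) {
    u <- readMatrixTsv(file.path(dir, "U.tsv"))
    v <- readMatrixTsv(file.path(dir, "V.tsv"))
    d <- as.numeric(readLines(file.path(dir, "D.tsv")))
    bed <- utils::read.table(file.path(dir, "bins.bed"), sep = "\t")
    gr <- GenomicRanges::GRanges(bed[[1]],
                                 IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
    S4Vectors::mcols(gr)$binIndex <- bed[[4]]
    td <- utils::read.table(file.path(dir, "tracks.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE,
                            colClasses = "character", na.strings = "")
    methods::new("LatentFactorModel", U = u, D = d, V = v, binRanges = gr,
                 trackData = S4Vectors::DataFrame(td))
}

# Shared writer for tracks x bins real matrices (SV matrices, normalized
# maps, factor matrices).
writeMatrixTsv <- function(m, path, rowLabel = "row") {
    con <- file(path, "w")
    writeLines(paste(c(rowLabel, colnames(m) %||%
                       paste0("c", seq_len(ncol(m)))), collapse = "\t"), con)
    rn <- rownames(m) %||% paste0("r", seq_len(nrow(m)))
    for (i in seq_len(nrow(m)))
        writeLines(paste(c(rn[i], formatExact(m[i, ])), collapse = "\t"), con)
    close(con)
    invisible(path)
}

readMatrixTsv <- function(path) {
    lines <- readLines(path)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    m <- t(vapply(body, function(f) as.numeric(f[-1]),
                  numeric(length(header) - 1L)))
    if (length(header) == 2L) m <- matrix(m, ncol = 1L)
    rownames(m) <- vapply(body, `[[`, character(1), 1L)
    colnames(m) <- header[-1]
    m
}
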
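# Generics and accessors for the core classes.

#' Extract the tracks-by-bins value matrix
#'
#' Returns the analysis-facing orientation of an object's value matrix:
#' tracks (samples) as rows, genomic bins as columns, with track identifiers
#' as row names and \code{"chrom:start-end"} (BED coordinates) bin labels as
#' column names.
#'
#' @param x a ChIPMap, TransformedMap or NormalizedMap.
#' @return numeric matrix, N tracks x M bins.
#' @export
setGeneric("chipValues", function(x) standardGeneric("chipValues"))

#' Genomic bin coordinates of an object
#' @param x an object carrying bins (ChIPMap, TransformedMap, NormalizedMap,
#'   LatentFactorModel).
#' @return GRanges, one range per bin, in matrix column order.
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Per-track metadata of an object
#' @param x an object carrying tracks.
#' @return DataFrame with one row per track.
#' @export
setGeneric("trackData", function(x) standardGeneric("trackData"))

#' Number of tracks / genomic bins
#' @param x an object carrying tracks or bins.
#' @return integer count.
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname nTracks
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

setMethod("chipValues", "ChIPMap", function(x) {
    m <- t(SummarizedExperiment::assay(x, "score"))
    rownames(m) <- as.character(SummarizedExperiment::colData(x)$trackId)
    colnames(m) <- binLabels(SummarizedExperiment::rowRanges(x))
    m
})
setMethod("chipValues", "TransformedMap", function(x) x@values)
setMethod("chipValues", "NormalizedMap", function(x) x@values)

setMethod("binRanges", "ChIPMap",
    function(x) SummarizedExperiment::rowRanges(x))
setMethod("binRanges", "TransformedMap", function(x) x@binRanges)
setMethod("binRanges", "NormalizedMap", function(x) x@binRanges)
setMethod("binRanges", "LatentFactorModel", function(x) x@binRanges)

setMethod("trackData", "ChIPMap",
    function(x) SummarizedExperiment::colData(x))
setMethod("trackData", "TransformedMap", function(x) x@trackData)
setMethod("trackData", "NormalizedMap", function(x) x@trackData)
setMethod("trackData", "LatentFactorModel", function(x) x@trackData)

setMethod("nTracks", "ChIPMap", function(x) ncol(x))
setMethod("nTracks", "TransformedMap", function(x) nrow(x@values))
setMethod("nTracks", "NormalizedMap", function(x) nrow(x@values))
setMethod("nTracks", "LatentFactorModel", function(x) nrow(x@U))

setMethod("nBins", "ChIPMap", function(x) nrow(x))
setMethod("nBins", "TransformedMap", function(x) ncol(x@values))
setMethod("nBins", "NormalizedMap", function(x) ncol(x@values))
setMethod("nBins", "LatentFactorModel", function(x) nrow(x@V))

#' Build mode of a ChIPMap
#' @param x a ChIPMap.
#' @return \code{"high_specificity"} or \code{"high_coverage"}.
#' @export
chipMode <- function(x) {
    stopifnot(is(x, "ChIPMap"))
    x@mode
}

#' Surrogate-variable accessors
#'
#' \code{svMatrix} returns the tracks-by-SVs matrix of unit-norm surrogate
#' variables; \code{svLabels} the covariate labels attached to each SV;
#' \code{svAssociations} the SV-by-covariate p-value matrix; and
#' \code{svProtected} the protection flags.
#'
#' @param x a SurrogateVariableSet (or NormalizedMap for \code{svProtected}).
#' @return see description.
#' @export
svMatrix <- function(x) x@svMatrix

#' @rdname svMatrix
#' @export
svLabels <- function(x) x@labels

#' @rdname svMatrix
#' @export
svAssociations <- function(x) x@associations

#' @rdname svMatrix
#' @export
svProtected <- function(x) x@protectedFlags

#' @rdname svMatrix
#' @export
nSignificantSVs <- function(x) ncol(x@svMatrix)

#' Latent factor model accessors
#'
#' \code{trackLoadings} returns \eqn{U} (track singular vectors),
#' \code{binLoadings} \eqn{V} (bin singular vectors), \code{singularValues}
#' \eqn{D}, \code{binFactorScores} the bin factor score matrix
#' \eqn{G = V D} and \code{sampleFactorScores} the sample factor score
#' matrix \eqn{S = U D}.
#'
#' @param x a LatentFactorModel.
#' @return numeric matrix or vector; see description.
#' @export
trackLoadings <- function(x) x@U

#' @rdname trackLoadings
#' @export
binLoadings <- function(x) x@V

#' @rdname trackLoadings
#' @export
singularValues <- function(x) x@D

#' @rdname trackLoadings
#' @export
binFactorScores <- function(x) {
    sweep(x@V, 2, x@D, "*")
}

#' @rdname trackLoadings
#' @export
sampleFactorScores <- function(x) {
    sweep(x@U, 2, x@D, "*")
}

#' Number of latent factors in a model
#' @param x a LatentFactorModel.
#' @return integer K.
#' @export
nFactors <- function(x) length(x@D)

#' Query result accessors
#' @param x a QueryResult.
#' @return see description: \code{factorScores} the per-factor weighted
#'   squared-cosine scores, \code{factorRanking} the descending-score
#'   permutation, \code{mappedBins} model bin indices hit by the query,
#'   \code{unmappedLoci} loci without reference coverage.
#' @export
factorScores <- function(x) x@factorScores

#' @rdname factorScores
#' @export
factorRanking <- function(x) x@ranking

#' @rdname factorScores
#' @export
mappedBins <- function(x) x@mappedBins

#' @rdname factorScores
#' @export
unmappedLoci <- function(x) x@unmappedLoci

#' @rdname factorScores
#' @export
hasCoverage <- function(x) length(x@mappedBins) > 0L

setMethod("show", "ChIPMap", function(object) {
    cat(sprintf("ChIPMap (%s): %d tracks x %d bins\n", object@mode,
                nTracks(object), nBins(object)))
    callNextMethod()
})

setMethod("show", "TransformedMap", function(object) {
    cat(sprintf(
        "TransformedMap: %d tracks x %d bins (pseudocount %g, %d bins dropped)\n",
        nTracks(object), nBins(object), object@pseudocount,
        object@nDroppedBins))
})

setMethod("show", "SurrogateVariableSet", function(object) {
    cat(sprintf("SurrogateVariableSet: %d significant SVs over %d tracks\n",
                ncol(object@svMatrix), nrow(object@svMatrix)))
    if (length(object@labels)) {
        lab <- vapply(object@labels, function(l)
            if (length(l)) paste(l, collapse = ",") else "-", character(1))
        cat("  labels:", paste(sprintf("SV%d:%s", seq_along(lab), lab),
                               collapse = " "), "\n")
    }
})

setMethod("show", "NormalizedMap", function(object) {
    cat(sprintf(
        "NormalizedMap: %d tracks x %d bins (%d SVs removed, %d kept)\n",
        nTracks(object), nBins(object), length(object@removedSVs),
        length(object@keptSVs)))
})

setMethod("show", "LatentFactorModel", function(object) {
    ve <- if (length(object@D) && sum(object@D^2) > 0)
        object@D^2 / sum(object@D^2) else numeric(0)
    cat(sprintf("LatentFactorModel: %d factors (%d tracks x %d bins)\n",
                nFactors(object), nTracks(object), nBins(object)))
    if (length(ve))
        cat("  variance explained (top):",
            paste(sprintf("%.1f%%", 100 * utils::head(ve, 3)),
                  collapse = ", "), "\n")
})

setMethod("show", "FactorAnnotation", function(object) {
    cat(sprintf("FactorAnnotation: factor %d, %d terms\n",
                object@factorIndex, nrow(object@terms)))
})

setMethod("show", "QueryResult", function(object) {
    if (!hasCoverage(object)) {
        cat("QueryResult: no coverage (0 mapped bins,",
            nrow(object@unmappedLoci), "unmapped loci)\n")
    } else {
        cat(sprintf(
            "QueryResult: %d mapped bins, %d unmapped loci; top factor %d (score %.3f)\n",
            length(object@mappedBins), nrow(object@unmappedLoci),
            object@ranking[1], object@factorScores[object@ranking[1]]))
    }
})

setMethod("show", "SyntheticDesign", function(object) {
    cat(sprintf(
        "SyntheticDesign: %d tracks, %d planted + %d batch factors, %d genome bins\n",
        object@nTracks, length(object@plantedFactors),
        length(object@batchFactors),
        sum(ceiling(object@chromSizes / object@binSize))))
})
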
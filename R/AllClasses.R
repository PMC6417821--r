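#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowRanges colData
NULL

#' ChIPMap: a binned ChIP-seq feature matrix
#'
#' A \code{ChIPMap} stores the aggregated peak-significance matrix built by
#' \code{\link{buildChIPMap}}: genomic bins as rows (with their coordinates as
#' \code{rowRanges}) and ChIP-seq tracks as columns (with per-track peak
#' counts and covariates in \code{colData}).  The single assay \code{"score"}
#' holds aggregated \eqn{-\log_{10}} q-values, non-negative everywhere, and
#' every bin retained in the object was hit by at least one peak.
#'
#' The analysis-facing orientation (tracks \eqn{N} by bins \eqn{M}) is
#' available through \code{\link{chipValues}}.
#'
#' @slot mode character; \code{"high_specificity"} (top-peaks filtered) or
#'   \code{"high_coverage"} (all peaks).
#' @seealso \code{\link{buildChIPMap}}, \code{\link{chipValues}}
#' @export
setClass("ChIPMap",
    contains = "RangedSummarizedExperiment",
    representation(mode = "character"))

setValidity("ChIPMap", function(object) {
    msg <- character(0)
    if (!object@mode %in% c("high_specificity", "high_coverage"))
        msg <- c(msg, "mode must be 'high_specificity' or 'high_coverage'")
    if (!"score" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'score' is required")
    else {
        a <- SummarizedExperiment::assay(object, "score")
        if (any(a < 0)) msg <- c(msg, "scores must be >= 0")
        if (nrow(a) > 0 && any(rowSums(a != 0) == 0))
            msg <- c(msg, "every bin must have at least one non-zero score")
    }
    if (length(msg)) msg else TRUE
})

#' TransformedMap: log-transformed, centered, scaled ChIP-map
#'
#' Produced by \code{\link{transformMap}}.  Values are oriented tracks (rows)
#' by bins (columns); each column has mean zero and unit standard deviation.
#' The per-bin means and scales used are retained for reproducibility.
#'
#' @slot values numeric matrix, tracks x bins.
#' @slot binRanges GRanges of the surviving bins.
#' @slot trackData DataFrame of per-track metadata.
#' @slot columnMeans,columnScales per-bin statistics applied after the log.
#' @slot pseudocount pseudocount added before the log.
#' @slot nDroppedBins number of zero-variance bins dropped.
#' @export
setClass("TransformedMap",
    representation(values = "matrix", binRanges = "GRanges",
                   trackData = "DataFrame", columnMeans = "numeric",
                   columnScales = "numeric", pseudocount = "numeric",
                   nDroppedBins = "integer"))

setValidity("TransformedMap", function(object) {
    msg <- character(0)
    if (ncol(object@values) != length(object@binRanges))
        msg <- c(msg, "ncol(values) must equal length(binRanges)")
    if (nrow(object@values) != nrow(object@trackData))
        msg <- c(msg, "nrow(values) must equal nrow(trackData)")
    if (ncol(object@values) != length(object@columnMeans) ||
        ncol(object@values) != length(object@columnScales))
        msg <- c(msg, "columnMeans/columnScales must match ncol(values)")
    if (length(msg)) msg else TRUE
})

#' SurrogateVariableSet: estimated surrogate variables with covariate labels
#'
#' Produced by \code{\link{estimateSurrogateVariables}} and annotated by
#' \code{\link{associateSVs}}.  Each column of \code{svMatrix} is one
#' surrogate variable (unit Euclidean norm); \code{associations} holds the
#' p-value of the univariate regression of each SV on each testable covariate,
#' \code{labels} the covariates attached to each SV at the chosen threshold,
#' and \code{protectedFlags} whether an SV is protected from removal.
#'
#' @slot svMatrix numeric matrix, tracks x SVs, unit-norm columns.
#' @slot singularValues the singular values of the retained SVs.
#' @slot permutationQuantiles the parallel-analysis thresholds each retained
#'   component exceeded.
#' @slot associations p-value matrix, SVs x covariates (NA when untestable).
#' @slot labels list of character vectors, one per SV.
#' @slot protectedFlags logical, one per SV.
#' @slot skippedCovariates covariates that could not be tested, with reason.
#' @slot alphaAssoc the association threshold used for labelling.
#' @export
setClass("SurrogateVariableSet",
    representation(svMatrix = "matrix", singularValues = "numeric",
                   permutationQuantiles = "numeric",
                   associations = "ANY", labels = "list",
                   protectedFlags = "logical",
                   skippedCovariates = "character", alphaAssoc = "numeric"))

setValidity("SurrogateVariableSet", function(object) {
    msg <- character(0)
    s <- ncol(object@svMatrix)
    if (s > 0) {
        nrm <- sqrt(colSums(object@svMatrix^2))
        if (any(abs(nrm - 1) > 1e-6))
            msg <- c(msg, "SV columns must have unit Euclidean norm")
    }
    if (length(object@labels) && length(object@labels) != s)
        msg <- c(msg, "labels must have one entry per SV")
    if (length(object@protectedFlags) && length(object@protectedFlags) != s)
        msg <- c(msg, "protectedFlags must have one entry per SV")
    if (length(msg)) msg else TRUE
})

#' NormalizedMap: residual ChIP-map after surrogate-variable regression
#'
#' Produced by \code{\link{regressOutSVs}}.  The residual matrix \eqn{W}
#' (tracks x bins) is orthogonal to every removed surrogate variable.
#'
#' @slot values numeric residual matrix, tracks x bins.
#' @slot binRanges,trackData carried bin/track metadata.
#' @slot removedSVs,keptSVs indices into the SurrogateVariableSet.
#' @slot svSet the (label-updated) SurrogateVariableSet used.
#' @export
setClass("NormalizedMap",
    representation(values = "matrix", binRanges = "GRanges",
                   trackData = "DataFrame", removedSVs = "integer",
                   keptSVs = "integer", svSet = "SurrogateVariableSet"))

#' LatentFactorModel: SVD of the normalized ChIP-map
#'
#' Thin singular value decomposition \eqn{W = U D V^T} of an
#' \eqn{N \times M} normalized ChIP-map, with \eqn{U} the track (sample)
#' singular vectors, \eqn{D} the non-increasing singular values and \eqn{V}
#' the genomic-bin singular vectors.  The factor score matrices
#' \eqn{G = V D} (bins) and \eqn{S = U D} (samples) are available through
#' \code{\link{binFactorScores}} and \code{\link{sampleFactorScores}}.
#'
#' @slot U numeric matrix N x K, orthonormal columns.
#' @slot D numeric length K, non-increasing, >= 0.
#' @slot V numeric matrix M x K, orthonormal columns.
#' @slot binRanges GRanges of the M bins.
#' @slot trackData DataFrame of the N tracks.
#' @export
setClass("LatentFactorModel",
    representation(U = "matrix", D = "numeric", V = "matrix",
                   binRanges = "GRanges", trackData = "DataFrame"))

setValidity("LatentFactorModel", function(object) {
    msg <- character(0)
    k <- length(object@D)
    if (ncol(object@U) != k || ncol(object@V) != k)
        msg <- c(msg, "U and V must have one column per singular value")
    if (k > 1 && any(diff(object@D) > 1e-8))
        msg <- c(msg, "singular values must be non-increasing")
    if (any(object@D < 0)) msg <- c(msg, "singular values must be >= 0")
    if (nrow(object@V) != length(object@binRanges))
        msg <- c(msg, "nrow(V) must equal length(binRanges)")
    if (length(msg)) msg else TRUE
})

#' FactorAnnotation: ranked enrichment terms for one latent factor
#'
#' Terms parsed from a GREAT result table, sorted ascending by binomial FDR
#' (ties by binomial p-value, then term id).
#'
#' @slot factorIndex which latent factor the terms annotate.
#' @slot terms data.frame with columns ontology, termId, termName, binomP,
#'   binomFdr, binomFold.
#' @export
setClass("FactorAnnotation",
    representation(factorIndex = "integer", terms = "data.frame"))

setValidity("FactorAnnotation", function(object) {
    msg <- character(0)
    need <- c("ontology", "termId", "termName", "binomP", "binomFdr",
              "binomFold")
    if (!all(need %in% names(object@terms)))
        msg <- c(msg, paste("terms must have columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(object@terms) > 1 && is.unsorted(object@terms$binomFdr))
        msg <- c(msg, "terms must be sorted ascending by binomFdr")
    if (length(msg)) msg else TRUE
})

#' QueryResult: ranked latent factors for a set of query loci
#'
#' Produced by \code{\link{rankFactors}}.  \code{factorScores} holds the
#' weighted squared-cosine score of every latent factor for the mapped bins
#' (summing to one when at least one bin mapped); \code{ranking} is the
#' descending-score permutation.  A query whose loci all fall outside the
#' reference bins yields a "no coverage" result with zero mapped bins.
#'
#' @slot mappedBins integer bin indices into the model's bins.
#' @slot binWeights aggregated per-bin weights (same length as mappedBins).
#' @slot unmappedLoci data.frame describing loci without reference coverage.
#' @slot factorScores numeric, one score per latent factor.
#' @slot ranking integer permutation, best factor first.
#' @slot annotations list of FactorAnnotation, possibly empty.
#' @export
setClass("QueryResult",
    representation(mappedBins = "integer", binWeights = "numeric",
                   unmappedLoci = "data.frame", factorScores = "numeric",
                   ranking = "integer", annotations = "list"))

setValidity("QueryResult", function(object) {
    msg <- character(0)
    if (length(object@mappedBins) != length(object@binWeights))
        msg <- c(msg, "binWeights must match mappedBins")
    if (length(object@mappedBins) > 0) {
        if (abs(sum(object@factorScores) - 1) > 1e-6)
            msg <- c(msg, "factor scores must sum to 1 when bins mapped")
        if (length(object@ranking) != length(object@factorScores))
            msg <- c(msg, "ranking must be a permutation of the factors")
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticDesign: planted-structure design for a synthetic peak corpus
#'
#' Describes a synthetic ChIP-seq corpus with known ("planted") latent
#' structure: biological factors tied to covariate labels, technical batch
#' factors, Gaussian noise, and a score floor imitating a q-value-thresholded
#' peak-calling corpus.  Built by \code{\link{syntheticDesign}} and realised
#' on disk by \code{\link{generateCorpus}}.
#'
#' @slot nTracks number of ChIP-seq tracks.
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot binSize genomic bin width (bp).
#' @slot plantedFactors list of biological factors; each a list with
#'   \code{name}, \code{covariate}, \code{trackLoading} (+/-1 per track),
#'   \code{bins} (genome bin indices of the support) and \code{delta}
#'   (score amplitude).
#' @slot batchFactors list of technical factors, same shape.
#' @slot covariates data.frame of per-track labels (trackId + columns).
#' @slot missingRate fraction of metadata cells blanked.
#' @slot noiseSd standard deviation of the Gaussian score noise.
#' @slot baseScore baseline \eqn{-\log_{10}} q-value of a planted peak.
#' @slot scoreFloor minimum emitted score (corpus q-value threshold).
#' @slot jitterPeaks emit peaks jittered across bin boundaries.
#' @slot seed RNG seed; corpora are byte-identical per seed.
#' @export
setClass("SyntheticDesign",
    representation(nTracks = "integer", chromSizes = "numeric",
                   binSize = "integer", plantedFactors = "list",
                   batchFactors = "list", covariates = "data.frame",
                   missingRate = "numeric", noiseSd = "numeric",
                   baseScore = "numeric", scoreFloor = "numeric",
                   jitterPeaks = "logical", seed = "integer"))

setValidity("SyntheticDesign", function(object) {
    msg <- character(0)
    facs <- c(object@plantedFactors, object@batchFactors)
    for (f in facs) {
        if (length(f$trackLoading) != object@nTracks)
            msg <- c(msg, "each factor's trackLoading must cover all tracks")
    }
    if (length(object@plantedFactors) >= 2) {
        tl <- vapply(object@plantedFactors, `[[`, numeric(object@nTracks),
                     "trackLoading")
        g <- crossprod(tl)
        if (any(abs(g[upper.tri(g)]) > 1e-8))
            msg <- c(msg, "planted track loadings must be mutually orthogonal")
        supports <- lapply(object@plantedFactors, `[[`, "bins")
        for (i in seq_along(supports)) for (j in seq_len(i - 1L))
            if (length(intersect(supports[[i]], supports[[j]])))
                msg <- c(msg, "planted bin supports must be disjoint")
        amps <- vapply(object@plantedFactors, `[[`, numeric(1), "delta")
        if (anyDuplicated(amps) || is.unsorted(rev(amps)))
            msg <- c(msg, "planted amplitudes must be distinct and ordered")
    }
    if (length(msg)) msg else TRUE
})
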
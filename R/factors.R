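# Latent factor discovery: thin SVD of the normalized ChIP-map and the
# contribution / squared-cosine scoring systems for bins and samples.

#' Decompose a normalized ChIP-map into latent factors
#'
#' Computes the thin singular value decomposition \eqn{W = U D V^T} with
#' \eqn{K = \min(N, M, \code{kMax})}.  Singular values in \eqn{D} give the
#' magnitude of each latent factor; the columns of \eqn{U} and \eqn{V}
#' summarise the association of tracks and genomic bins with each factor.
#' Each factor's sign is fixed so the largest-magnitude entry of its
#' \eqn{V} column is positive, making pipelines reproducible across
#' linear-algebra backends.
#'
#' @param norm a \code{\linkS4class{NormalizedMap}},
#'   \code{\linkS4class{TransformedMap}} or plain numeric matrix
#'   (tracks x bins).
#' @param kMax maximum number of factors (default: full thin rank).
#' @param bins,tracks bin \code{GRanges} / track \code{DataFrame} metadata
#'   when \code{norm} is a bare matrix; taken from the object otherwise.
#' @return a \code{\linkS4class{LatentFactorModel}}.
#' @export
decomposeMap <- function(norm, kMax = NULL, bins = NULL, tracks = NULL) {
    if (methods::is(norm, "NormalizedMap") ||
        methods::is(norm, "TransformedMap")) {
        w <- chipValues(norm)
        br <- binRanges(norm)
        td <- trackData(norm)
    } else {
        w <- as.matrix(norm)
        br <- bins %||% GenomicRanges::GRanges(
            "chrUnk", IRanges::IRanges(seq_len(ncol(w)), seq_len(ncol(w))))
        td <- tracks %||% S4Vectors::DataFrame(
            trackId = rownames(w) %||% paste0("track", seq_len(nrow(w))))
    }
    if (any(!is.finite(w))) stop("matrix contains non-finite entries")
    k <- min(nrow(w), ncol(w))
    if (!is.null(kMax)) k <- min(k, kMax)
    sv <- svd(w, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    u <- sv$u
    v <- sv$v
    s <- signFix(v)
    v <- sweep(v, 2, s, "*")
    u <- sweep(u, 2, s, "*")
    dimnames(u) <- list(as.character(td$trackId), paste0("LF", seq_len(k)))
    dimnames(v) <- list(binLabels(br), paste0("LF", seq_len(k)))
    methods::new("LatentFactorModel", U = u, D = d, V = v, binRanges = br,
                 trackData = td)
}

#' Variance explained by each latent factor
#'
#' Fraction of total variance carried by factor \eqn{k},
#' \eqn{d_k^2 / \sum_{k'} d_{k'}^2}, with cumulative fractions.
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @return data.frame with columns \code{factor}, \code{varianceExplained},
#'   \code{cumulative}.
#' @export
varianceExplained <- function(model) {
    d <- singularValues(model)
    tot <- sum(d^2)
    if (tot == 0) stop("all singular values are zero")
    fr <- d^2 / tot
    data.frame(factor = seq_along(d), varianceExplained = fr,
               cumulative = cumsum(fr))
}

#' Genomic bin contribution scores for one factor
#'
#' The contribution of bin \eqn{j} to factor \eqn{k} is the squared bin
#' singular-vector entry, \eqn{\mathrm{cntr}_k(j) = v_{j,k}^2}.  Because
#' \eqn{V} is orthonormal the scores sum to one over bins, so each score is
#' the percent-importance of a bin for the factor.
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param k factor index, \eqn{1 \le k \le K}.
#' @return named numeric vector over bins, summing to 1.
#' @export
binContributions <- function(model, k) {
    if (k < 1 || k > nFactors(model)) stop("factor index k out of range")
    v <- binLoadings(model)[, k]
    stats::setNames(v^2, rownames(binLoadings(model)))
}

#' Genomic bin squared-cosine scores
#'
#' The squared cosine of bin \eqn{j} on factor \eqn{k} is
#' \eqn{\cos^2_j(k) = g_{j,k}^2 / \sum_{k'} g_{j,k'}^2} with
#' \eqn{G = V D} the bin factor score matrix; scores sum to one over
#' factors, giving the relative importance of each latent factor for a bin.
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param j bin index; if \code{NULL}, the full bins-by-factors matrix is
#'   returned.
#' @return numeric vector over factors (or M x K matrix), rows summing to 1.
#' @export
binSquaredCosines <- function(model, j = NULL) {
    g2 <- binFactorScores(model)^2
    tot <- rowSums(g2)
    if (!is.null(j)) {
        if (j < 1 || j > nBins(model)) stop("bin index j out of range")
        if (tot[j] == 0)
            stop("bin ", rownames(binLoadings(model))[j],
                 " has all-zero factor scores")
        return(g2[j, ] / tot[j])
    }
    if (any(tot == 0))
        stop("bin(s) with all-zero factor scores: ",
             paste(utils::head(rownames(binLoadings(model))[tot == 0], 5),
                   collapse = ", "))
    sweep(g2, 1, tot, "/")
}

#' Sample contribution and squared-cosine scores
#'
#' With \eqn{S = U D} the sample factor score matrix, the contribution of
#' sample \eqn{i} to factor \eqn{k} is
#' \eqn{s_{i,k}^2 / \sum_{i'} s_{i',k}^2} (columns sum to one) and the
#' squared cosine of factor \eqn{k} for sample \eqn{i} is
#' \eqn{s_{i,k}^2 / \sum_{k'} s_{i,k'}^2} (rows sum to one).
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @return list with elements \code{contribution} (N x K, columns sum to 1;
#'   columns of zero singular values are NA and listed in
#'   \code{excludedFactors}) and \code{squaredCosine} (N x K, rows sum
#'   to 1).
#' @export
sampleScores <- function(model) {
    s2 <- sampleFactorScores(model)^2
    colTot <- colSums(s2)
    excluded <- which(colTot == 0)
    cntr <- sweep(s2, 2, ifelse(colTot == 0, NA_real_, colTot), "/")
    rowTot <- rowSums(s2)
    cosine <- sweep(s2, 1, rowTot, "/")
    list(contribution = cntr, squaredCosine = cosine,
         excludedFactors = excluded)
}

#' Top bins of a latent factor
#'
#' Bins ranked by descending contribution score for factor \eqn{k}; the top
#' 5,000 bins per factor form the default GREAT enrichment query.  Ties are
#' broken by (chrom, start).
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param k factor index.
#' @param nBins number of bins to return (default 5000; all if fewer).
#' @return \code{GRanges} of the top bins, best first, with metadata column
#'   \code{contribution}.
#' @export
topBinsForFactor <- function(model, k, nBins = 5000) {
    if (nBins < 1) stop("nBins must be >= 1")
    cntr <- binContributions(model, k)
    gr <- binRanges(model)
    o <- order(-cntr, as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), method = "radix")
    top <- o[seq_len(min(nBins, length(o)))]
    out <- gr[top]
    S4Vectors::mcols(out)$contribution <- unname(cntr[top])
    out
}
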
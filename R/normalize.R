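# Batch normalization: log/center/scale transform, surrogate-variable
# estimation by parallel analysis, covariate labelling of SVs, and removal
# of non-protected SVs by QR regression.

#' Log-transform, center and scale a ChIP-map
#'
#' Applies \code{log(raw + pseudocount)} (log first: centering can produce
#' negatives), then per-bin centering and scaling to unit standard
#' deviation.  Bins with zero variance after the log are dropped with a
#' diagnostic count.
#'
#' @param chipmap a \code{\linkS4class{ChIPMap}}.
#' @param pseudocount positive value added before the log (default 1;
#'   scores are \eqn{-\log_{10} q \ge 0}).
#' @return a \code{\linkS4class{TransformedMap}}.
#' @export
transformMap <- function(chipmap, pseudocount = 1) {
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    x <- log(chipValues(chipmap) + pseudocount)
    sds <- apply(x, 2, stats::sd)
    drop <- sds == 0 | !is.finite(sds)
    nDropped <- sum(drop)
    if (nDropped > 0)
        message(nDropped, " zero-variance bin(s) dropped before scaling")
    x <- x[, !drop, drop = FALSE]
    mu <- colMeans(x)
    sc <- apply(x, 2, stats::sd)
    z <- scale(x, center = mu, scale = sc)
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    methods::new("TransformedMap", values = unclass(z),
                 binRanges = binRanges(chipmap)[!drop],
                 trackData = trackData(chipmap),
                 columnMeans = unname(mu), columnScales = unname(sc),
                 pseudocount = pseudocount, nDroppedBins = as.integer(nDropped))
}

#' Estimate surrogate variables by parallel analysis
#'
#' Surrogate variables are taken as the left singular vectors of the
#' transformed matrix whose singular values exceed the
#' \eqn{(1 - \code{sigLevel})} quantile of the singular values obtained from
#' \code{nPermutations} independent column-wise permutations of the matrix
#' (the Buja-Eyuboglu parallel-analysis criterion).  Permuting each bin
#' column independently preserves the marginal score distributions while
#' destroying cross-track structure, so retained components capture
#' variation shared across rows and columns at a frequency greater than
#' expected by chance.  Each retained SV has unit norm and its sign is fixed
#' so the largest-magnitude loading is positive.
#'
#' @param tmap a \code{\linkS4class{TransformedMap}}.
#' @param nPermutations number of column permutations (default 100).
#' @param sigLevel per-component significance level (default 0.05).
#' @param seed RNG seed; the estimate is deterministic given the seed.
#' @return a \code{\linkS4class{SurrogateVariableSet}} (labels empty until
#'   \code{\link{associateSVs}} is run).
#' @export
estimateSurrogateVariables <- function(tmap, nPermutations = 100,
                                       sigLevel = 0.05, seed = 1) {
    if (nPermutations < 1) stop("nPermutations must be >= 1")
    x <- chipValues(tmap)
    if (nrow(x) < 3) stop("need at least 3 tracks to estimate SVs")
    sv <- svd(x)
    k <- length(sv$d)
    dPerm <- withSeed(seed, {
        t(vapply(seq_len(nPermutations), function(b) {
            xp <- apply(x, 2, sample)
            matrixSingularValues(xp)[seq_len(k)]
        }, numeric(k)))
    })
    thresh <- apply(dPerm, 2, stats::quantile, probs = 1 - sigLevel,
                    names = FALSE)
    sig <- which(sv$d > thresh)
    u <- sv$u[, sig, drop = FALSE]
    if (length(sig)) {
        s <- signFix(u)
        u <- sweep(u, 2, s, "*")
    }
    colnames(u) <- if (length(sig)) paste0("SV", seq_along(sig))
    rownames(u) <- rownames(x)
    methods::new("SurrogateVariableSet", svMatrix = u,
                 singularValues = sv$d[sig],
                 permutationQuantiles = thresh[sig],
                 associations = NULL, labels = rep(list(character(0)),
                                                   length(sig)),
                 protectedFlags = logical(length(sig)),
                 skippedCovariates = character(0), alphaAssoc = NA_real_)
}

#' Label surrogate variables by association with known covariates
#'
#' For each (SV, covariate) pair, fits the univariate linear regression of
#' the SV on the covariate over the tracks with that covariate observed
#' (categorical covariates are one-hot encoded; the overall F-test p-value
#' is recorded; for a continuous covariate this equals the slope t-test).
#' An SV is labelled with every covariate whose p-value falls below
#' \code{alphaAssoc}.  Covariates with fewer than 3 non-missing tracks, a
#' single observed level, or too few residual degrees of freedom are skipped
#' with a diagnostic, not an error.
#'
#' @param svs a \code{\linkS4class{SurrogateVariableSet}}.
#' @param metadata data.frame of per-track covariates with a \code{trackId}
#'   column; empty cells / NA are missing.
#' @param alphaAssoc labelling threshold (default \code{1e-30}, appropriate
#'   for corpus-scale track counts; raise it for small cohorts).
#' @return the input set with \code{associations} and \code{labels} filled.
#' @export
associateSVs <- function(svs, metadata, alphaAssoc = 1e-30) {
    u <- svMatrix(svs)
    s <- ncol(u)
    if (!"trackId" %in% names(metadata))
        stop("metadata must have a 'trackId' column")
    md <- metadata[match(rownames(u), metadata$trackId), , drop = FALSE]
    covs <- setdiff(names(md), "trackId")
    skipped <- character(0)
    pmat <- matrix(NA_real_, nrow = s, ncol = length(covs),
                   dimnames = list(colnames(u), covs))
    for (cv in covs) {
        v <- md[[cv]]
        obs <- !is.na(v) & v != ""
        if (sum(obs) < 3) {
            skipped <- c(skipped, paste0(cv, " (", sum(obs),
                                         " non-missing tracks)"))
            next
        }
        vv <- v[obs]
        num <- suppressWarnings(as.numeric(vv))
        isNum <- !anyNA(num)
        pred <- if (isNum) num else factor(vv)
        if (!isNum && nlevels(pred) < 2) {
            skipped <- c(skipped, paste0(cv, " (single level)"))
            next
        }
        if (!isNum && nlevels(pred) >= sum(obs)) {
            skipped <- c(skipped, paste0(cv, " (no residual df)"))
            next
        }
        for (i in seq_len(s)) {
            fit <- stats::lm(u[obs, i] ~ pred)
            # a perfect fit (SV identical to a covariate pattern) warns in
            # summary.lm; that is the designed use-case here
            fs <- suppressWarnings(summary(fit)$fstatistic)
            pmat[i, cv] <- if (is.null(fs)) NA_real_ else
                stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
        }
    }
    if (length(skipped))
        message("skipped covariates: ", paste(skipped, collapse = "; "))
    labels <- lapply(seq_len(s), function(i) {
        p <- pmat[i, ]
        names(p)[!is.na(p) & p < alphaAssoc]
    })
    methods::initialize(svs, associations = pmat, labels = labels,
                        skippedCovariates = skipped, alphaAssoc = alphaAssoc)
}

#' Remove non-protected surrogate variables by QR regression
#'
#' SVs labelled with any covariate in \code{protectedCovariates} are
#' excluded from the regressor set (protecting biological signal of
#' interest, e.g. antibody).  The remaining SVs plus an intercept form the
#' design matrix; residuals are computed through one QR factorization
#' applied simultaneously to all bin columns.  Note that unlabelled SVs are
#' removed: when metadata are missing for a biologically relevant covariate,
#' its variation cannot be protected.
#'
#' @param tmap a \code{\linkS4class{TransformedMap}}.
#' @param svs a label-annotated \code{\linkS4class{SurrogateVariableSet}}.
#' @param protectedCovariates character vector of covariate names to
#'   protect.
#' @return a \code{\linkS4class{NormalizedMap}}; if every SV is protected
#'   the values are returned unchanged with a warning.
#' @export
regressOutSVs <- function(tmap, svs, protectedCovariates = character(0)) {
    if (ncol(svMatrix(svs)) > 0 && is.null(svAssociations(svs)))
        stop("SV labels not computed; run associateSVs() first")
    u <- svMatrix(svs)
    prot <- vapply(svLabels(svs), function(l)
        length(intersect(l, protectedCovariates)) > 0, logical(1))
    svs2 <- methods::initialize(svs, protectedFlags = prot)
    removed <- which(!prot)
    kept <- which(prot)
    y <- chipValues(tmap)
    if (ncol(u) > 0 && length(removed) == 0L) {
        warning("all surrogate variables are protected; nothing regressed out")
        resid <- y
    } else {
        design <- cbind(intercept = 1, u[, removed, drop = FALSE])
        resid <- stats::lm.fit(design, y)$residuals
        dimnames(resid) <- dimnames(y)
    }
    methods::new("NormalizedMap", values = resid,
                 binRanges = binRanges(tmap), trackData = trackData(tmap),
                 removedSVs = as.integer(removed), keptSVs = as.integer(kept),
                 svSet = svs2)
}

#' One-call normalization pipeline
#'
#' \code{transformMap}, \code{estimateSurrogateVariables},
#' \code{associateSVs} and \code{regressOutSVs} in sequence.
#'
#' @inheritParams transformMap
#' @inheritParams estimateSurrogateVariables
#' @inheritParams associateSVs
#' @inheritParams regressOutSVs
#' @param metadata per-track covariate data.frame (trackId column).
#' @return a \code{\linkS4class{NormalizedMap}}.
#' @export
normalizeChIPMap <- function(chipmap, metadata,
                             protectedCovariates = "antibody",
                             pseudocount = 1, nPermutations = 100,
                             sigLevel = 0.05, alphaAssoc = 1e-30, seed = 1) {
    tmap <- transformMap(chipmap, pseudocount)
    svs <- estimateSurrogateVariables(tmap, nPermutations, sigLevel, seed)
    svs <- associateSVs(svs, metadata, alphaAssoc)
    regressOutSVs(tmap, svs, protectedCovariates)
}
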
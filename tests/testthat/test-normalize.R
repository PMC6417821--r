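# Transform, surrogate-variable estimation, covariate labelling, QR removal.

# small ChIPMap from a raw tracks x bins matrix
chipMapFromMatrix <- function(x) {
    bins <- binGenome(stats::setNames(ncol(x) * 1000, "chr1"), 1000)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(score = t(x)), rowRanges = bins,
        colData = S4Vectors::DataFrame(
            trackId = paste0("t", seq_len(nrow(x))),
            nPeaksRaw = rep(1L, nrow(x)), nPeaksKept = rep(1L, nrow(x))))
    methods::new("ChIPMap", se, mode = "high_coverage")
}

test_that("transformMap logs, centers, scales and drops constant bins", {
    x <- rbind(c(0, 5, 3), c(exp(1) - 1, 5, 7))  # column 2 is constant
    cm <- chipMapFromMatrix(x)
    expect_message(tm <- transformMap(cm, pseudocount = 1),
                   "1 zero-variance bin")
    expect_equal(tm@nDroppedBins, 1L)
    z <- chipValues(tm)
    expect_equal(dim(z), c(2L, 2L))
    # column [0, e-1] with pseudocount 1: log -> [0, 1]; centered/scaled
    # gives a symmetric pair about zero
    expect_equal(unname(z[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
    expect_equal(sum(z[, 1]), 0, tolerance = 1e-12)
    expect_true(all(abs(colMeans(z)) < 1e-8))
    expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
    expect_error(transformMap(cm, pseudocount = 0), "pseudocount")
})

test_that("column means vanish on an arbitrary fixture", {
    set.seed(5)
    x <- matrix(rexp(20 * 15, rate = 0.1), 20, 15)
    tm <- transformMap(chipMapFromMatrix(x))
    expect_true(all(abs(colMeans(chipValues(tm))) < 1e-8))
})

test_that("parallel analysis retains few components under the null", {
    retained <- vapply(1:5, function(s) {
        set.seed(100 + s)
        x <- matrix(rnorm(20 * 120), 20, 120)
        x <- scale(x)
        tm <- methods::new("TransformedMap", values = unclass(x),
            binRanges = binGenome(c(chr1 = 120e3), 1000),
            trackData = S4Vectors::DataFrame(trackId = paste0("t", 1:20)),
            columnMeans = numeric(120), columnScales = rep(1, 120),
            pseudocount = 1, nDroppedBins = 0L)
        nSignificantSVs(estimateSurrogateVariables(tm, nPermutations = 30,
                                                   sigLevel = 0.05,
                                                   seed = s))
    }, integer(1))
    # expect ~5% of 20 components per seed; allow up to 20%
    expect_true(mean(retained) <= 0.20 * 20)
})

test_that("a planted rank-1 batch is detected and recovered", {
    set.seed(9)
    u <- rep(c(1, -1), each = 10)
    v <- rnorm(150)
    x <- 3 * outer(u, v) + matrix(rnorm(20 * 150), 20, 150)
    tm <- methods::new("TransformedMap", values = scale(x),
        binRanges = binGenome(c(chr1 = 150e3), 1000),
        trackData = S4Vectors::DataFrame(trackId = paste0("t", 1:20)),
        columnMeans = numeric(150), columnScales = rep(1, 150),
        pseudocount = 1, nDroppedBins = 0L)
    svs <- estimateSurrogateVariables(tm, nPermutations = 30, seed = 2)
    expect_gte(nSignificantSVs(svs), 1)
    expect_gt(abs(cor(svMatrix(svs)[, 1], u)), 0.9)
    # determinism
    svs2 <- estimateSurrogateVariables(tm, nPermutations = 30, seed = 2)
    expect_identical(svMatrix(svs), svMatrix(svs2))
    expect_error(estimateSurrogateVariables(tm, nPermutations = 0),
                 "nPermutations")
})

test_that("SV estimation is invariant to track order up to sign", {
    set.seed(21)
    u <- rnorm(18)
    x <- 4 * outer(u, rnorm(100)) + matrix(rnorm(18 * 100), 18, 100)
    mkTm <- function(m) methods::new("TransformedMap", values = scale(m),
        binRanges = binGenome(c(chr1 = 1e5), 1000),
        trackData = S4Vectors::DataFrame(trackId = paste0("t", 1:18)),
        columnMeans = numeric(100), columnScales = rep(1, 100),
        pseudocount = 1, nDroppedBins = 0L)
    perm <- sample(18)
    svA <- estimateSurrogateVariables(mkTm(x), nPermutations = 30, seed = 4)
    svB <- estimateSurrogateVariables(mkTm(x[perm, ]), nPermutations = 30,
                                      seed = 4)
    expect_equal(nSignificantSVs(svA), nSignificantSVs(svB))
    a <- svMatrix(svA)[perm, 1]
    b <- svMatrix(svB)[, 1]
    expect_gt(abs(cor(a, b)), 0.999)
})

test_that("associateSVs labels perfect associations and skips degenerates", {
    set.seed(31)
    n <- 16
    onehot <- rep(c(1, 0), each = n / 2)
    sv1 <- onehot - mean(onehot)
    sv1 <- sv1 / sqrt(sum(sv1^2))
    sv2 <- rnorm(n)
    sv2 <- sv2 - mean(sv2)
    sv2 <- sv2 / sqrt(sum(sv2^2))
    u <- cbind(SV1 = sv1, SV2 = sv2)
    rownames(u) <- paste0("t", 1:n)
    svs <- methods::new("SurrogateVariableSet", svMatrix = u,
        singularValues = c(2, 1), permutationQuantiles = c(1, 1),
        associations = NULL, labels = rep(list(character(0)), 2),
        protectedFlags = logical(2), skippedCovariates = character(0),
        alphaAssoc = NA_real_)
    md <- data.frame(trackId = paste0("t", 1:n),
                     group = rep(c("A", "B"), each = n / 2),
                     allMissing = NA_character_,
                     oneLevel = "same")
    expect_message(out <- associateSVs(svs, md, alphaAssoc = 1e-30),
                   "skipped covariates")
    p <- svAssociations(out)
    expect_lt(p["SV1", "group"], 1e-30)    # numerically ~0
    expect_true(is.na(p["SV1", "allMissing"]))
    expect_true(is.na(p["SV1", "oneLevel"]))
    expect_equal(svLabels(out)[[1]], "group")
    # SV independent of the covariate: no label at a stringent alpha
    expect_gt(p["SV2", "group"], 1e-10)
    expect_length(svLabels(out)[[2]], 0)
    expect_length(out@skippedCovariates, 2)
})

test_that("null association p-values are roughly uniform", {
    set.seed(77)
    n <- 30
    ps <- replicate(200, {
        sv <- rnorm(n)
        g <- factor(sample(c("A", "B"), n, TRUE))
        fit <- summary(lm(sv ~ g))$fstatistic
        pf(fit[1], fit[2], fit[3], lower.tail = FALSE)
    })
    expect_gt(ks.test(ps, "punif")$p.value, 1e-4)
})

test_that("a planted batch direction agrees with the reference SVA package", {
    skip_if_not_installed("sva")
    set.seed(19)
    u <- rep(c(1, -1), each = 10)
    x <- 4 * outer(u, rnorm(200)) + matrix(rnorm(20 * 200), 20, 200)
    x <- scale(x)
    tm <- methods::new("TransformedMap", values = unclass(x),
        binRanges = binGenome(c(chr1 = 2e5), 1000),
        trackData = S4Vectors::DataFrame(trackId = paste0("t", 1:20)),
        columnMeans = numeric(200), columnScales = rep(1, 200),
        pseudocount = 1, nDroppedBins = 0L)
    ours <- svMatrix(estimateSurrogateVariables(tm, nPermutations = 30,
                                                seed = 3))[, 1]
    # independent reference: the Bioconductor SVA implementation on the
    # same matrix (features x samples orientation); the primary variable
    # is an arbitrary covariate unrelated to the batch
    z <- rnorm(20)
    mod <- stats::model.matrix(~z)
    mod0 <- stats::model.matrix(~1, data.frame(z))
    ref <- suppressMessages(
        sva::sva(t(unclass(x)), mod = mod, mod0 = mod0, n.sv = 1))
    expect_gt(abs(cor(ours, ref$sv[, 1])), 0.9)
    expect_gt(abs(cor(u, ref$sv[, 1])), 0.9)
})

test_that("regressOutSVs removes only non-protected SVs via QR", {
    set.seed(41)
    n <- 10; m <- 50
    x <- matrix(rnorm(n * m), n, m)
    x <- scale(x)
    tm <- methods::new("TransformedMap", values = unclass(x),
        binRanges = binGenome(c(chr1 = m * 1000), 1000),
        trackData = S4Vectors::DataFrame(trackId = paste0("t", 1:n)),
        columnMeans = numeric(m), columnScales = rep(1, m),
        pseudocount = 1, nDroppedBins = 0L)
    u <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
    colnames(u) <- c("SV1", "SV2")
    rownames(u) <- paste0("t", 1:n)
    svs <- methods::new("SurrogateVariableSet", svMatrix = u,
        singularValues = c(2, 1), permutationQuantiles = c(1, 1),
        associations = matrix(c(1e-40, 0.5, 0.5, 1e-40), 2, 2,
            dimnames = list(c("SV1", "SV2"), c("antibody", "batchvar"))),
        labels = list("antibody", "batchvar"), protectedFlags = logical(2),
        skippedCovariates = character(0), alphaAssoc = 1e-30)

    nm <- regressOutSVs(tm, svs, "antibody")
    expect_equal(nm@removedSVs, 2L)
    expect_equal(nm@keptSVs, 1L)
    w <- chipValues(nm)
    # residual columns orthogonal to every removed SV
    cosines <- abs(crossprod(u[, 2], w)) /
        (sqrt(sum(u[, 2]^2)) * sqrt(colSums(w^2)))
    expect_lt(max(cosines), 1e-8)
    # QR residuals equal normal-equation residuals
    X <- cbind(1, u[, 2])
    beta <- solve(crossprod(X), crossprod(X, chipValues(tm)))
    expect_lt(max(abs(w - (chipValues(tm) - X %*% beta))), 1e-8)
    # idempotence
    tm2 <- methods::initialize(tm, values = w)
    w2 <- chipValues(regressOutSVs(tm2, svs, "antibody"))
    expect_lt(max(abs(w2 - w)), 1e-8)

    # all SVs protected: unchanged with a warning
    expect_warning(nmAll <- regressOutSVs(tm, svs,
                                          c("antibody", "batchvar")),
                   "protected")
    expect_equal(chipValues(nmAll), chipValues(tm))
    expect_true(all(svProtected(nmAll@svSet)))
})
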
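# Internal helpers shared across modules.

#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
#' @importFrom stats lm pf quantile rnorm runif setNames sd
#' @importFrom utils head read.table write.table
NULL

# Canonical chromosome naming: "chr"-prefixed; bare names normalised on read.
normalizeChrom <- function(x) {
    x <- as.character(x)
    ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# Bin label in BED coordinates (0-based half-open), e.g. "chr1:0-1000".
binLabels <- function(gr) {
    paste0(as.character(GenomicRanges::seqnames(gr)), ":",
           GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}

# Format doubles so that a write/read round trip is bit-exact.
formatExact <- function(x) {
    sprintf("%.17g", x)
}

# Order of ranges by (chrom, start) with chromosome names compared as strings
# (deterministic, locale-independent via the C collation of factor levels).
genomeOrder <- function(chrom, start) {
    order(as.character(chrom), start, method = "radix")
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so seeded operations do not perturb user code.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

# Singular values of a matrix, cheap path when one dimension is small.
matrixSingularValues <- function(x) {
    n <- nrow(x); m <- ncol(x)
    if (n <= m) {
        ev <- eigen(tcrossprod(x), symmetric = TRUE, only.values = TRUE)$values
    } else {
        ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
    }
    sqrt(pmax(ev, 0))
}

# Fix the sign of each column of `v` so its largest-magnitude entry is
# positive; returns the +1/-1 multipliers applied.
signFix <- function(v) {
    if (ncol(v) == 0L) return(numeric(0))
    vapply(seq_len(ncol(v)), function(k) {
        col <- v[, k]
        i <- which.max(abs(col))
        if (col[i] < 0) -1 else 1
    }, numeric(1))
}
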
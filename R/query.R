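# Query pipeline: map user loci to reference bins, rank latent factors by
# weighted squared-cosine score, report annotated functions; GWAS-catalog
# coverage and rank-robustness analyses.

#' Construct a query set of genomic loci
#'
#' A query set holds SNPs and/or intervals with optional positive weights
#' (for example GWAS effect sizes) and source identifiers (rsIDs).  SNP
#' positions are 1-based (GWAS-catalog convention); intervals may instead be
#' given as BED-style 0-based half-open \code{start}/\code{end}.
#'
#' @param chrom chromosome names (normalised to the \code{"chr"} prefix).
#' @param pos 1-based SNP positions (exclusive with \code{start}/\code{end}).
#' @param start,end 0-based half-open interval coordinates.
#' @param ids optional per-locus labels (default \code{locus1, ...}).
#' @param weights optional positive per-locus weights (default uniform).
#' @return \code{GRanges} with metadata columns \code{sourceId} and
#'   \code{weight}.
#' @export
querySet <- function(chrom, pos = NULL, start = NULL, end = NULL,
                     ids = NULL, weights = NULL) {
    if (!is.null(pos)) {
        if (any(is.na(pos)) || any(pos < 1))
            stop("SNP positions must be positive 1-based integers")
        gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                                     IRanges::IRanges(pos, pos))
    } else {
        if (is.null(start) || is.null(end)) stop("need pos or start/end")
        if (any(start >= end)) stop("interval start must be < end")
        gr <- GenomicRanges::GRanges(normalizeChrom(chrom),
                                     IRanges::IRanges(start + 1L, end))
    }
    n <- length(gr)
    if (is.null(ids)) ids <- paste0("locus", seq_len(n))
    if (is.null(weights)) weights <- rep(1 / n, n)
    if (length(weights) != n || any(weights <= 0))
        stop("weights must match the loci and be > 0")
    S4Vectors::mcols(gr)$sourceId <- as.character(ids)
    S4Vectors::mcols(gr)$weight <- as.numeric(weights)
    gr
}

#' Read query loci from a TSV or BED file
#'
#' @param path SNP TSV with columns id, chrom, pos (header optional,
#'   detected), or a BED3+ interval file when \code{format = "bed"}.
#' @param format \code{"snp"} or \code{"bed"}.
#' @return a query-set \code{GRanges} (see \code{\link{querySet}}).
#' @export
readQueryLoci <- function(path, format = c("snp", "bed")) {
    format <- match.arg(format)
    if (format == "bed") {
        tab <- utils::read.table(path, sep = "\t", header = FALSE)
        return(querySet(tab[[1]], start = tab[[2]], end = tab[[3]],
                        ids = if (ncol(tab) >= 4) tab[[4]]))
    }
    first <- readLines(path, n = 1)
    hasHeader <- grepl("chrom|pos|id", tolower(first))
    tab <- utils::read.table(path, sep = "\t", header = hasHeader,
                             colClasses = "character")
    if (hasHeader) {
        names(tab) <- tolower(names(tab))
        querySet(tab$chrom, pos = as.integer(tab$pos), ids = tab$id)
    } else {
        querySet(tab[[2]], pos = as.integer(tab[[3]]), ids = tab[[1]])
    }
}

#' Map query loci onto the reference bins of a model
#'
#' A SNP maps to the unique reference bin containing its position; an
#' interval maps to every overlapping reference bin.  Loci falling in
#' genomic regions absent from the reference (bins without any ChIP-seq
#' peak were removed) are returned as unmapped, never silently dropped.
#' Weights of multiple loci landing in one bin are summed.
#'
#' @param qs query \code{GRanges} from \code{\link{querySet}}.
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @return list with \code{bins} (model bin indices), \code{weights}
#'   (aggregated, parallel to \code{bins}) and \code{unmapped} (data.frame
#'   of uncovered loci).
#' @export
mapQueryToBins <- function(qs, model) {
    if (is.null(S4Vectors::mcols(qs)$weight))
        S4Vectors::mcols(qs)$weight <- rep(1 / length(qs), length(qs))
    br <- binRanges(model)
    qsIn <- qs
    offChrom <- !(as.character(GenomicRanges::seqnames(qs)) %in%
                  GenomeInfoDb::seqlevels(br))
    hits <- GenomicRanges::findOverlaps(qsIn[!offChrom], br, minoverlap = 1L)
    qIdx <- which(!offChrom)[S4Vectors::queryHits(hits)]
    bIdx <- S4Vectors::subjectHits(hits)
    mappedLoci <- unique(qIdx)
    unmappedIdx <- setdiff(seq_along(qs), mappedLoci)
    unmapped <- data.frame(
        sourceId = S4Vectors::mcols(qs)$sourceId[unmappedIdx],
        chrom = as.character(GenomicRanges::seqnames(qs))[unmappedIdx],
        start = GenomicRanges::start(qs)[unmappedIdx] - 1L,
        end = GenomicRanges::end(qs)[unmappedIdx])
    if (length(bIdx) == 0L)
        return(list(bins = integer(0), weights = numeric(0),
                    unmapped = unmapped))
    w <- S4Vectors::mcols(qs)$weight[qIdx]
    agg <- rowsum(w, bIdx)
    list(bins = as.integer(rownames(agg)), weights = as.numeric(agg),
         unmapped = unmapped)
}

#' Rank latent factors for a set of mapped bins
#'
#' Computes the weighted average of genomic bin squared-cosine scores over
#' the mapped bins \eqn{J},
#' \eqn{\cos^2_J(k) = \sum_{j \in J} w_j \cos^2_j(k) / \sum_{j \in J} w_j},
#' and ranks factors by descending score.  With a single bin this reduces
#' exactly to that bin's squared-cosine profile.  Weights default to
#' uniform.  A query with no mapped bins yields an explicit "no coverage"
#' result, not an error.
#'
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param qs either a query \code{GRanges} or the list returned by
#'   \code{\link{mapQueryToBins}}.
#' @param annotations optional list of \code{FactorAnnotation} keyed by
#'   factor index.
#' @return a \code{\linkS4class{QueryResult}}.
#' @export
rankFactors <- function(model, qs, annotations = list()) {
    mapped <- if (is.list(qs) && !methods::is(qs, "GRanges")) qs
              else mapQueryToBins(qs, model)
    if (length(mapped$bins) == 0L) {
        return(methods::new("QueryResult", mappedBins = integer(0),
                            binWeights = numeric(0),
                            unmappedLoci = mapped$unmapped,
                            factorScores = numeric(0), ranking = integer(0),
                            annotations = list()))
    }
    cosines <- binSquaredCosines(model)[mapped$bins, , drop = FALSE]
    w <- mapped$weights / sum(mapped$weights)
    scores <- as.numeric(crossprod(cosines, w))
    names(scores) <- colnames(binLoadings(model))
    ranking <- order(-scores, seq_along(scores), method = "radix")
    methods::new("QueryResult", mappedBins = mapped$bins,
                 binWeights = mapped$weights,
                 unmappedLoci = mapped$unmapped, factorScores = scores,
                 ranking = as.integer(ranking), annotations = annotations)
}

#' Report the top latent factors of a query
#'
#' Tabulates the top factors with their weighted squared-cosine score,
#' variance explained and the best enriched terms per ontology.  A reported
#' factor lacking annotation is kept with an empty term list and a warning.
#'
#' @param result a \code{\linkS4class{QueryResult}}.
#' @param model the \code{\linkS4class{LatentFactorModel}} queried.
#' @param annotations list of \code{FactorAnnotation} keyed by factor index
#'   (as character); defaults to those stored in the result.
#' @param nFactors number of factors to report (default 5).
#' @param nTerms number of top terms per ontology (default 3).
#' @return data.frame with one row per (factor, ontology term) and columns
#'   rank, factor, score, varianceExplained, ontology, termId, termName,
#'   binomFdr.
#' @export
queryReport <- function(result, model, annotations = NULL, nFactors = 5,
                        nTerms = 3) {
    if (!hasCoverage(result)) {
        warning("query has no reference coverage; empty report")
        return(data.frame(rank = integer(0), factor = integer(0),
                          score = numeric(0), varianceExplained = numeric(0),
                          ontology = character(0), termId = character(0),
                          termName = character(0), binomFdr = numeric(0)))
    }
    if (is.null(annotations)) annotations <- result@annotations
    ve <- varianceExplained(model)
    top <- utils::head(factorRanking(result), nFactors)
    rows <- lapply(seq_along(top), function(r) {
        k <- top[r]
        base <- data.frame(rank = r, factor = k,
                           score = factorScores(result)[k],
                           varianceExplained = ve$varianceExplained[k])
        ann <- annotations[[as.character(k)]]
        if (is.null(ann)) {
            warning("no annotation available for factor ", k)
            return(cbind(base, ontology = NA_character_,
                         termId = NA_character_, termName = NA_character_,
                         binomFdr = NA_real_))
        }
        terms <- annotationTerms(ann)
        keep <- unlist(lapply(split(seq_len(nrow(terms)), terms$ontology),
                              utils::head, nTerms))
        terms <- terms[sort(keep), , drop = FALSE]
        if (nrow(terms) == 0L)
            return(cbind(base, ontology = NA_character_,
                         termId = NA_character_, termName = NA_character_,
                         binomFdr = NA_real_))
        cbind(base[rep(1, nrow(terms)), , drop = FALSE],
              terms[, c("ontology", "termId", "termName", "binomFdr")])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' GWAS-catalog coverage of a reference model
#'
#' Filters out SNPs classified as intergenic (to focus on SNPs associated
#' with transcriptional cis-regulation), maps the remainder onto the
#' reference bins, and summarises per-trait and overall counts and mapped
#' percentages.  Coverage denominators are the post-intergenic-filter
#' counts.
#'
#' @param catalog data.frame in GWAS-catalog layout, or a path to its TSV.
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param columnMap named list locating the required columns (defaults
#'   match the GWAS-catalog export: \code{SNPS}, \code{CHR_ID},
#'   \code{CHR_POS}, \code{DISEASE/TRAIT}, \code{CONTEXT}).
#' @return data.frame with columns trait, nTotal, nMapped, pctMapped; the
#'   last row \code{"<overall>"} aggregates all traits.
#' @export
gwasCatalogCoverage <- function(catalog, model,
                                columnMap = list(rsid = "SNPS",
                                                 chrom = "CHR_ID",
                                                 pos = "CHR_POS",
                                                 trait = "DISEASE/TRAIT",
                                                 context = "CONTEXT")) {
    if (is.character(catalog))
        catalog <- utils::read.table(catalog, sep = "\t", header = TRUE,
                                     check.names = FALSE, quote = "",
                                     colClasses = "character")
    missing <- setdiff(unlist(columnMap), names(catalog))
    if (length(missing))
        stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
    ctx <- catalog[[columnMap$context]]
    keep <- !grepl("intergenic", ctx, ignore.case = TRUE)
    cat2 <- catalog[keep, , drop = FALSE]
    if (nrow(cat2) == 0L) {
        warning("no SNPs remain after the intergenic filter")
        return(data.frame(trait = character(0), nTotal = integer(0),
                          nMapped = integer(0), pctMapped = numeric(0)))
    }
    pos <- suppressWarnings(as.integer(cat2[[columnMap$pos]]))
    ok <- !is.na(pos) & nzchar(cat2[[columnMap$chrom]])
    cat2 <- cat2[ok, , drop = FALSE]
    pos <- pos[ok]
    qs <- querySet(cat2[[columnMap$chrom]], pos = pos,
                   ids = cat2[[columnMap$rsid]])
    br <- binRanges(model)
    offChrom <- !(as.character(GenomicRanges::seqnames(qs)) %in%
                  GenomeInfoDb::seqlevels(br))
    mappedFlag <- logical(length(qs))
    hits <- GenomicRanges::findOverlaps(qs[!offChrom], br, minoverlap = 1L)
    mappedFlag[which(!offChrom)[unique(S4Vectors::queryHits(hits))]] <- TRUE
    trait <- cat2[[columnMap$trait]]
    tab <- do.call(rbind, lapply(split(seq_along(trait), trait), function(i)
        data.frame(trait = trait[i[1]], nTotal = length(i),
                   nMapped = sum(mappedFlag[i]))))
    tab <- tab[order(tab$trait), , drop = FALSE]
    tab <- rbind(tab, data.frame(trait = "<overall>",
                                 nTotal = length(qs),
                                 nMapped = sum(mappedFlag)))
    tab$pctMapped <- 100 * tab$nMapped / tab$nTotal
    rownames(tab) <- NULL
    tab
}

#' Rank-robustness of the group-level factor identification
#'
#' Step 1: ranks factors for all loci jointly (weighted squared-cosine
#' average) and takes the top \code{nGroupFactors} group factors.  Step 2:
#' for each locus independently, records the rank of each group factor in
#' that locus's own single-locus ranking.  Reports, for each group factor
#' and each rank cutoff \eqn{n}, the fraction of loci whose own ranking
#' places the group factor within the top \eqn{n}, together with the
#' cumulative frequency \eqn{n / K} expected under a uniform-rank null.
#'
#' @param qs query \code{GRanges} (at least 2 mappable loci).
#' @param model a \code{\linkS4class{LatentFactorModel}}.
#' @param nGroupFactors number of group-level factors to follow (default 5).
#' @return data.frame with columns groupFactor, rank, cumulativeFrequency,
#'   nullExpectation.
#' @export
robustnessAnalysis <- function(qs, model, nGroupFactors = 5) {
    groupRes <- rankFactors(model, qs)
    if (!hasCoverage(groupRes)) stop("no query locus maps to the reference")
    k <- nFactors(model)
    groupTop <- utils::head(factorRanking(groupRes), nGroupFactors)

    perLocus <- lapply(seq_along(qs), function(i) {
        res <- rankFactors(model, qs[i])
        if (!hasCoverage(res)) return(NULL)
        # rank position of every factor in this locus's own ranking
        match(seq_len(k), factorRanking(res))
    })
    perLocus <- perLocus[!vapply(perLocus, is.null, logical(1))]
    if (length(perLocus) < 2)
        stop("robustness analysis needs at least 2 mappable loci")
    ranks <- do.call(rbind, perLocus)  # loci x factors

    out <- do.call(rbind, lapply(groupTop, function(f) {
        cf <- vapply(seq_len(k), function(n) mean(ranks[, f] <= n),
                     numeric(1))
        data.frame(groupFactor = f, rank = seq_len(k),
                   cumulativeFrequency = cf,
                   nullExpectation = seq_len(k) / k)
    }))
    rownames(out) <- NULL
    out
}
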
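# Functional annotation of latent factors: export of GREAT query BEDs and
# ingestion of GREAT enrichment result tables.  The GREAT web service itself
# is never called; queries are exported and exported result tables parsed,
# keeping builds hermetic.

#' Column aliases for GREAT result tables
#'
#' GREAT's export column names vary by version and export route; this map
#' translates them onto the canonical fields.  Users can extend it for
#' other dialects.
#'
#' @return named list of character vectors of acceptable column names.
#' @export
greatColumnAliases <- function() {
    list(ontology = c("Ontology", "# Ontology", "ontology"),
         termId = c("ID", "TermID", "term_id", "Term ID"),
         termName = c("Desc", "TermName", "term_name", "Description", "name"),
         binomP = c("BinomP", "BinomRawPValue", "binom_p",
                    "Binom Raw P-Value"),
         binomFdr = c("BinomFdrQ", "BinomFDR", "binom_fdr", "Binom FDR Q-Val"),
         binomFold = c("RegionFoldEnrich", "BinomFoldEnrichment",
                       "binom_fold", "Binom Fold Enrichment"))
}

#' Export a GREAT query BED
#'
#' Writes the given bins as a BED3 file (0-based half-open coordinates,
#' sorted by chrom then start), suitable for submission to GREAT.  The
#' default factor query is the top 5,000 bins by contribution score (see
#' \code{\link{topBinsForFactor}}).
#'
#' @param bins non-empty \code{GRanges}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportGreatQuery <- function(bins, path) {
    if (length(bins) == 0L) stop("cannot export an empty bin list")
    o <- genomeOrder(GenomicRanges::seqnames(bins),
                     GenomicRanges::start(bins))
    bins <- bins[o]
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                      start = GenomicRanges::start(bins) - 1L,
                      end = GenomicRanges::end(bins))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Parse a GREAT enrichment result table
#'
#' Header-driven parse of a GREAT TSV export: the binomial-test summary
#' statistics (binomial p-value, binomial FDR q-value, binomial fold
#' enrichment) are collected for every term.  Rows whose statistics fail
#' numeric parsing are dropped with a diagnostic.
#'
#' @param path TSV file with named columns.
#' @param ontology ontology name (\code{"GO"}, \code{"HPO"}, \code{"MGI"})
#'   used when the table has no ontology column.
#' @param aliases column-alias map, see \code{\link{greatColumnAliases}}.
#' @return data.frame of enriched terms with columns \code{ontology},
#'   \code{termId}, \code{termName}, \code{binomP}, \code{binomFdr},
#'   \code{binomFold}, in file order.
#' @export
parseGreatResults <- function(path, ontology = NULL,
                              aliases = greatColumnAliases()) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, comment.char = "",
                             quote = "\"", colClasses = "character")
    pick <- function(field, required = TRUE) {
        hit <- intersect(aliases[[field]], names(tab))
        if (length(hit) == 0L) {
            if (required)
                stop("GREAT table ", path, " is missing a '", field,
                     "' column (any of: ",
                     paste(aliases[[field]], collapse = ", "), ")")
            return(NULL)
        }
        tab[[hit[1]]]
    }
    out <- data.frame(
        ontology = pick("ontology", required = is.null(ontology)) %||%
            rep(ontology, nrow(tab)),
        termId = pick("termId"),
        termName = pick("termName"),
        binomP = suppressWarnings(as.numeric(pick("binomP"))),
        binomFdr = suppressWarnings(as.numeric(pick("binomFdr"))),
        binomFold = suppressWarnings(as.numeric(pick("binomFold"))),
        stringsAsFactors = FALSE)
    if (nrow(out) == 0L) return(out)
    bad <- is.na(out$binomP) | is.na(out$binomFdr) | is.na(out$binomFold)
    if (any(bad))
        message(sum(bad), " row(s) dropped from ", basename(path),
                " (non-numeric statistics)")
    out[!bad, , drop = FALSE]
}

#' Attach ranked enrichment terms to a latent factor
#'
#' Sorts terms ascending by binomial FDR (ties by binomial p-value, then
#' term id) and optionally applies an FDR ceiling.
#'
#' @param k factor index.
#' @param terms data.frame of enriched terms from
#'   \code{\link{parseGreatResults}}.
#' @param fdrCeiling optional maximum binomial FDR to retain.
#' @return a \code{\linkS4class{FactorAnnotation}}.
#' @export
annotateFactor <- function(k, terms, fdrCeiling = NULL) {
    if (!is.null(fdrCeiling))
        terms <- terms[terms$binomFdr <= fdrCeiling, , drop = FALSE]
    o <- order(terms$binomFdr, terms$binomP, terms$termId, method = "radix")
    methods::new("FactorAnnotation", factorIndex = as.integer(k),
                 terms = terms[o, , drop = FALSE])
}

#' Annotation terms accessor
#' @param x a FactorAnnotation.
#' @return data.frame of terms, sorted by binomial FDR.
#' @export
annotationTerms <- function(x) x@terms

#' Annotate all factors from a directory of GREAT result tables
#'
#' Expects files named \code{factor<k>.<ontology>.tsv} (as written by
#' \code{\link{generateGreatMock}}); terms across ontologies are pooled per
#' factor.
#'
#' @param dir directory of GREAT result TSVs.
#' @param fdrCeiling optional maximum binomial FDR.
#' @return named list of \code{FactorAnnotation}, one per factor index
#'   found.
#' @export
annotateFactorsFromDir <- function(dir, fdrCeiling = NULL) {
    files <- list.files(dir, pattern = "^factor[0-9]+\\..*\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0L) return(list())
    ks <- as.integer(sub("^factor([0-9]+)\\..*$", "\\1", basename(files)))
    onts <- sub("^factor[0-9]+\\.([^.]*)\\.tsv$", "\\1", basename(files))
    ann <- lapply(sort(unique(ks)), function(k) {
        idx <- which(ks == k)
        terms <- do.call(rbind, Map(function(f, o)
            parseGreatResults(f, ontology = toupper(o)), files[idx],
            onts[idx]))
        rownames(terms) <- NULL
        annotateFactor(k, terms, fdrCeiling)
    })
    names(ann) <- as.character(sort(unique(ks)))
    ann
}
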
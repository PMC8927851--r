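#' Construct a ValidPairSet from a records data.frame
#'
#' @param records data.frame with columns readID, chr1, pos1, strand1, chr2,
#'   pos2, strand2.
#' @param genome a \linkS4class{GenomeBins} carrying the chromosome universe.
#' @param nSkipped number of input lines dropped during parsing.
#' @export
validPairSet <- function(records, genome, nSkipped = 0L) {
    new("ValidPairSet", records = as.data.frame(records), genome = genome,
        nSkipped = as.integer(nSkipped))
}

#' Number of pairs
#' @param x a \linkS4class{ValidPairSet}.
#' @export
nPairs <- function(x) nrow(x@records)

#' Pair records
#' @param x a \linkS4class{ValidPairSet}.
#' @export
pairRecords <- function(x) x@records

#' Read a valid-pairs text file
#'
#' Tab-separated, no header, at least 7 columns: read id, chr1, pos1, strand1,
#' chr2, pos2, strand2 (further columns ignored) — the common valid-pairs
#' dialect of Hi-C preprocessing pipelines. Records on chromosomes absent from
#' \code{genome}, or with out-of-bounds positions, are skipped with a warning
#' (or abort the read in strict mode).
#'
#' @param path input file.
#' @param genome a \linkS4class{GenomeBins}.
#' @param strict abort on any invalid record instead of skipping.
#' @return a \linkS4class{ValidPairSet}; the skip count is in \code{@nSkipped}.
#' @export
readValidPairs <- function(path, genome, strict = FALSE) {
    if (!file.exists(path)) stop("cannot read valid-pairs file: ", path)
    dt <- suppressWarnings(  # fread warns separately on zero-byte files
        data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          colClasses = list(character = 1)))
    if (nrow(dt) == 0L) {
        warning("empty valid-pairs file: ", path)
        return(validPairSet(
            data.frame(readID = character(), chr1 = character(), pos1 = numeric(),
                       strand1 = character(), chr2 = character(), pos2 = numeric(),
                       strand2 = character()), genome))
    }
    if (ncol(dt) < 7L) stop("valid-pairs file must have >= 7 columns: ", path)
    rec <- data.frame(readID = as.character(dt[[1]]),
                      chr1 = as.character(dt[[2]]), pos1 = as.numeric(dt[[3]]),
                      strand1 = as.character(dt[[4]]),
                      chr2 = as.character(dt[[5]]), pos2 = as.numeric(dt[[6]]),
                      strand2 = as.character(dt[[7]]))
    len <- setNames(genome@chromLengths, genome@chromNames)
    ok <- rec$chr1 %in% genome@chromNames & rec$chr2 %in% genome@chromNames
    ok[ok] <- !is.na(rec$pos1[ok]) & !is.na(rec$pos2[ok]) &
        rec$pos1[ok] >= 1 & rec$pos2[ok] >= 1 &
        rec$pos1[ok] <= len[rec$chr1[ok]] & rec$pos2[ok] <= len[rec$chr2[ok]]
    nbad <- sum(!ok)
    if (nbad > 0L) {
        if (strict) stop(nbad, " invalid record(s) in ", path, " (strict mode)")
        warning(nbad, " invalid record(s) skipped in ", path)
    }
    validPairSet(rec[ok, , drop = FALSE], genome, nSkipped = nbad)
}

#' Write a valid-pairs text file
#'
#' @param pairs a \linkS4class{ValidPairSet}.
#' @param path destination.
#' @export
writeValidPairs <- function(pairs, path) {
    data.table::fwrite(pairs@records, path, sep = "\t",
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @describeIn validPairSet display method
#' @param object a \linkS4class{ValidPairSet}.
#' @export
setMethod("show", "ValidPairSet", function(object) {
    cis <- sum(object@records$chr1 == object@records$chr2)
    cat(sprintf("ValidPairSet: %d pairs (%d cis, %d trans), %d skipped at parse\n",
                nPairs(object), cis, nPairs(object) - cis, object@nSkipped))
})
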
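#' Build a genome binning scheme
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param binSize bin width B in bp.
#' @return A \linkS4class{GenomeBins}.
#' @examples
#' gb <- genomeBins(c(chrS = 1e6), binSize = 1e5)
#' nBins(gb)
#' @export
genomeBins <- function(chromLengths, binSize) {
    stopifnot(is.numeric(chromLengths), length(chromLengths) >= 1,
              !is.null(names(chromLengths)), binSize > 0)
    nb <- as.integer(ceiling(chromLengths / binSize))
    new("GenomeBins",
        chromNames = names(chromLengths),
        chromLengths = unname(as.numeric(chromLengths)),
        binSize = as.numeric(binSize),
        nBinsPerChrom = nb,
        offsets = as.integer(cumsum(c(0L, head(nb, -1L)))))
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @param binSize bin size for the returned \linkS4class{GenomeBins}.
#' @export
readChromSizes <- function(path, binSize) {
    cs <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            colClasses = c("character", "numeric"))
    genomeBins(setNames(cs$length, cs$chrom), binSize)
}

#' Write a chrom.sizes file
#' @param bins a \linkS4class{GenomeBins}.
#' @param path destination.
#' @export
writeChromSizes <- function(bins, path) {
    utils::write.table(
        data.frame(bins@chromNames, format(bins@chromLengths, scientific = FALSE, trim = TRUE)),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname genomeBins
#' @param x a \linkS4class{GenomeBins}.
#' @export
nBins <- function(x) sum(x@nBinsPerChrom)

#' Chromosome names of a binning scheme
#' @param x a \linkS4class{GenomeBins}.
#' @export
chromNames <- function(x) x@chromNames

#' Bin size (bp)
#' @param x a \linkS4class{GenomeBins} or \linkS4class{ContactMatrix}.
#' @export
binSize <- function(x) {
    if (is(x, "ContactMatrix")) x@bins@binSize else x@binSize
}

#' Per-bin table of a binning scheme
#'
#' @param x a \linkS4class{GenomeBins}.
#' @return data.frame with chrom, start (0-based), end (half-open), binID
#'   (0-based global index, matching triplet-matrix exports).
#' @export
binTable <- function(x) {
    chrom <- rep(x@chromNames, x@nBinsPerChrom)
    k <- unlist(lapply(x@nBinsPerChrom, function(n) seq_len(n) - 1L), use.names = FALSE)
    len <- rep(x@chromLengths, x@nBinsPerChrom)
    start <- k * x@binSize
    data.frame(chrom = chrom, start = start,
               end = pmin(start + x@binSize, len),
               binID = seq_len(sum(x@nBinsPerChrom)) - 1L)
}

#' Bins as genomic ranges
#' @param x a \linkS4class{GenomeBins}.
#' @return a \code{GRanges} (1-based closed intervals).
#' @export
binRanges <- function(x) {
    bt <- binTable(x)
    GenomicRanges::GRanges(bt$chrom,
        IRanges::IRanges(start = bt$start + 1, end = bt$end),
        seqlengths = setNames(x@chromLengths, x@chromNames))
}

# map (chrom, 1-based bp position) -> 1-based global bin index
globalBin <- function(bins, chrom, pos) {
    ci <- match(chrom, bins@chromNames)
    bins@offsets[ci] + ((pos - 1) %/% bins@binSize) + 1L
}

# per-chromosome 1-based global index ranges, as a named list
chromBinIdx <- function(bins) {
    setNames(lapply(seq_along(bins@chromNames), function(i) {
        (bins@offsets[i] + 1L):(bins@offsets[i] + bins@nBinsPerChrom[i])
    }), bins@chromNames)
}

#' @describeIn genomeBins display method
#' @param object a \linkS4class{GenomeBins}.
#' @export
setMethod("show", "GenomeBins", function(object) {
    cat(sprintf("GenomeBins: %d chromosome(s), bin size %s bp, %d bins\n",
                length(object@chromNames),
                format(object@binSize, big.mark = ","), nBins(object)))
})
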
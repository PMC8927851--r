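#' Write a per-bin track as bedGraph
#'
#' @param bins a \linkS4class{GenomeBins}.
#' @param values numeric per-bin values (NA bins skipped).
#' @param path destination.
#' @param name track name for the header line.
#' @export
writeBedGraph <- function(bins, values, path, name = "track") {
    stopifnot(length(values) == nBins(bins))
    bt <- binTable(bins)
    keep <- !is.na(values)
    con <- file(path, "w")
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
    if (any(keep))
        writeLines(sprintf("%s\t%d\t%d\t%g", bt$chrom[keep],
                           as.integer(bt$start[keep]),
                           as.integer(bt$end[keep]), values[keep]), con)
    close(con)
    invisible(path)
}

#' Write genomic segments as BED
#'
#' @param df data.frame with chrom, start (0-based), end and optionally name.
#' @param path destination.
#' @export
writeBed <- function(df, path) {
    nm <- if ("name" %in% names(df)) df$name else
        sprintf("region%d", seq_len(nrow(df)))
    con <- file(path, "w")
    if (nrow(df))
        writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom,
                           as.integer(df$start), as.integer(df$end), nm), con)
    close(con)
    invisible(path)
}

#' Contiguous A/B segments of a compartment track as a BED data.frame
#' @param track an oriented \linkS4class{CompartmentTrack}.
#' @export
compartmentSegments <- function(track) {
    bt <- binTable(track@bins)
    out <- NULL
    for (idx in chromBinIdx(track@bins)) {
        lab <- track@label[idx]
        r <- rle(ifelse(is.na(lab), ".", lab))
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        keep <- r$values %in% c("A", "B")
        if (any(keep))
            out <- rbind(out, data.frame(
                chrom = bt$chrom[idx[starts[keep]]],
                start = bt$start[idx[starts[keep]]],
                end = bt$end[idx[ends[keep]]],
                name = r$values[keep]))
    }
    if (is.null(out)) data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), name = character())
    else out
}

#' Write loops as washU long-range interaction text
#'
#' One line per loop: \code{chr\tstart\tend\tchr:start-end,score}.
#'
#' @param x a \linkS4class{LoopSet}.
#' @param bins the \linkS4class{GenomeBins} the loops were called on.
#' @param path destination.
#' @export
writeLongrange <- function(x, bins, path) {
    lp <- loopPixels(x)
    bt <- binTable(bins)
    ci <- chromBinIdx(bins)
    con <- file(path, "w")
    if (nrow(lp)) for (k in seq_len(nrow(lp))) {
        g1 <- ci[[lp$chrom[k]]][lp$i[k]]
        g2 <- ci[[lp$chrom[k]]][lp$j[k]]
        writeLines(sprintf("%s\t%d\t%d\t%s:%d-%d,%.2f",
            lp$chrom[k], as.integer(bt$start[g1]), as.integer(bt$end[g1]),
            lp$chrom[k], as.integer(bt$start[g2]), as.integer(bt$end[g2]),
            lp$fold_donut[k]), con)
    }
    close(con)
    invisible(path)
}

#' Write an SCC (or any square summary) matrix as a TSV heat-table
#' @param m numeric matrix with dimnames.
#' @param path destination.
#' @export
writeHeatTable <- function(m, path) {
    df <- data.frame(sample = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t")
    invisible(path)
}
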
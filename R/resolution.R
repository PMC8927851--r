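# depth at the percentile position of the descending-sorted coverage vector
percentileDepth <- function(depth, percentile) {
    sort(depth, decreasing = TRUE)[max(1L, ceiling(percentile * length(depth)))]
}

#' Map-resolution determination by percentile bin depth
#'
#' For each candidate bin size, computes the coverage of every genomic bin,
#' sorts bins by coverage in descending order, and reads the depth at the
#' 75th-, 80th- and 90th-percentile positions. A bin size is "achieved" when
#' the depth at the 80th-percentile position (configurable) reaches the depth
#' threshold; the finest achieved size is the map resolution. Coverage counts
#' pair ends by default (each valid pair contributes two ends), switchable to
#' midpoints (one count per pair).
#'
#' @param pairs a \linkS4class{ValidPairSet}.
#' @param genome a \linkS4class{GenomeBins} or named chromosome-length vector.
#' @param candidateSizes candidate bin sizes in bp; default the standard grid
#'   1 Mb down to 1 kb.
#' @param depthThreshold minimum depth (default 1000).
#' @param percentile decision percentile (default 0.80).
#' @param coverage "ends" (default) or "midpoints".
#' @return list of class \code{ResolutionReport}: \code{table} (data.frame
#'   with binSize, nBins, depth75, depth80, depth90, fracAbove, achieved),
#'   \code{finestAchieved} (bp, NA if none), and the parameters.
#' @export
mapResolution <- function(pairs, genome,
                          candidateSizes = c(1e6, 5e5, 2e5, 1e5, 4e4, 2e4,
                                             1e4, 5e3, 1e3),
                          depthThreshold = 1000, percentile = 0.80,
                          coverage = c("ends", "midpoints")) {
    coverage <- match.arg(coverage)
    lens <- if (is(genome, "GenomeBins"))
        setNames(genome@chromLengths, genome@chromNames) else genome
    r <- pairs@records
    candidateSizes <- sort(candidateSizes, decreasing = TRUE)
    rows <- lapply(candidateSizes, function(B) {
        bins <- genomeBins(lens, B)
        n <- nBins(bins)
        if (nrow(r) == 0L) {
            depth <- rep(0, n)
        } else if (coverage == "ends") {
            idx <- c(globalBin(bins, r$chr1, r$pos1),
                     globalBin(bins, r$chr2, r$pos2))
            depth <- tabulate(idx, nbins = n)
        } else {
            mid <- ifelse(r$chr1 == r$chr2, (r$pos1 + r$pos2) %/% 2, r$pos1)
            depth <- tabulate(globalBin(bins, r$chr1, mid), nbins = n)
        }
        at <- function(p) percentileDepth(depth, p)
        data.frame(binSize = B, nBins = n,
                   depth75 = at(0.75), depth80 = at(0.80), depth90 = at(0.90),
                   decisionDepth = at(percentile),
                   fracAbove = mean(depth > depthThreshold),
                   achieved = at(percentile) >= depthThreshold)
    })
    tab <- do.call(rbind, rows)
    finest <- if (any(tab$achieved)) min(tab$binSize[tab$achieved]) else NA_real_
    structure(list(table = tab, finestAchieved = finest,
                   depthThreshold = depthThreshold, percentile = percentile,
                   coverage = coverage),
              class = "ResolutionReport")
}

#' @export
print.ResolutionReport <- function(x, ...) {
    cat(sprintf("ResolutionReport (threshold %g at the %.0fth-percentile bin, %s coverage)\n",
                x$depthThreshold, 100 * x$percentile, x$coverage))
    print(x$table, row.names = FALSE)
    cat(if (is.na(x$finestAchieved)) "No candidate size achieved.\n" else
        sprintf("Finest achieved bin size: %s bp\n",
                format(x$finestAchieved, big.mark = ",", scientific = FALSE)))
    invisible(x)
}

#' Write a ResolutionReport to JSON
#' @param report a ResolutionReport.
#' @param path destination file.
#' @export
writeResolutionReport <- function(report, path) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
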
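#' A/B compartment eigenvector
#'
#' Per chromosome, computes the Pearson correlation matrix of the
#' observed/expected map's columns over unmasked bins and returns the
#' eigenvector of the largest eigenvalue (E1). The track is unoriented: the
#' global sign per chromosome is arbitrary until
#' \code{\link{orientCompartments}} is applied. Bins that are masked, all-NA
#' or of zero variance get NA.
#'
#' @param oe a \linkS4class{ContactMatrix} in "oe" state.
#' @param minBins minimum usable bins per chromosome (default 10).
#' @return a \linkS4class{CompartmentTrack} (labels unset until orientation).
#' @export
compartmentEigenvector <- function(oe, minBins = 10) {
    if (oe@state != "oe")
        stop("compartment calling expects an observed/expected matrix")
    n <- nBins(oe@bins)
    e1 <- rep(NA_real_, n)
    ev <- setNames(rep(NA_real_, length(oe@bins@chromNames)),
                   oe@bins@chromNames)
    ci <- chromBinIdx(oe@bins)
    for (ch in oe@bins@chromNames) {
        idx <- ci[[ch]]
        blk <- oe@mat[idx, idx, drop = FALSE]
        usable <- !oe@mask[idx] & colSums(!is.na(blk)) > 1 &
            apply(blk, 2, function(v) sd(v, na.rm = TRUE) > 0) %in% TRUE
        if (sum(usable) < minBins) {
            warning("chromosome ", ch, ": fewer than ", minBins,
                    " usable bins; skipped")
            next
        }
        C <- suppressWarnings(cor(blk[usable, usable, drop = FALSE],
                                  use = "pairwise.complete.obs"))
        C[!is.finite(C)] <- 0
        if (max(abs(C[upper.tri(C)])) == 0)
            stop("no compartment signal on ", ch,
                 ": degenerate correlation matrix")
        eg <- eigen(C, symmetric = TRUE)
        e1[idx[usable]] <- eg$vectors[, 1]
        pos <- pmax(eg$values, 0)
        ev[ch] <- pos[1] / sum(pos)
    }
    new("CompartmentTrack", bins = oe@bins, e1 = e1,
        label = rep(NA_character_, n), evShare = ev, oriented = FALSE,
        covariateName = NA_character_)
}

#' Orient an eigenvector track and assign A/B labels
#'
#' Per chromosome, negates E1 when its correlation with the covariate
#' (typically gene density; the active A compartment is gene-rich) is
#' negative, then labels bins A where E1 > 0 and B where E1 < 0.
#'
#' @param track an unoriented \linkS4class{CompartmentTrack}.
#' @param covariate numeric per-bin orientation covariate (global bin order).
#' @param covariateName recorded name.
#' @return the oriented, labeled track.
#' @export
orientCompartments <- function(track, covariate, covariateName = "covariate") {
    stopifnot(length(covariate) == nBins(track@bins))
    e1 <- track@e1
    for (idx in chromBinIdx(track@bins)) {
        ok <- !is.na(e1[idx]) & !is.na(covariate[idx])
        if (sum(ok) < 2) next
        if (sd(covariate[idx][ok]) == 0) {
            warning("constant covariate; orientation left as-is")
            next
        }
        if (sd(e1[idx][ok]) == 0) next
        if (cor(e1[idx][ok], covariate[idx][ok]) < 0)
            e1[idx] <- -e1[idx]
    }
    lab <- ifelse(is.na(e1) | e1 == 0, NA_character_,
                  ifelse(e1 > 0, "A", "B"))
    new("CompartmentTrack", bins = track@bins, e1 = e1, label = lab,
        evShare = track@evShare, oriented = TRUE,
        covariateName = covariateName)
}

#' Gene-density covariate from gene intervals
#'
#' Counts genes overlapping each bin (any overlap of at least 1 bp).
#'
#' @param bins a \linkS4class{GenomeBins}.
#' @param genes a \code{GRanges} or the path of a BED file.
#' @return numeric per-bin gene counts.
#' @export
geneDensity <- function(bins, genes) {
    if (is.character(genes)) genes <- rtracklayer::import(genes, format = "BED")
    GenomicRanges::countOverlaps(binRanges(bins), genes, minoverlap = 1L)
}

#' Compartment labels of a track
#' @param x a \linkS4class{CompartmentTrack}.
#' @export
compartmentLabels <- function(x) x@label

#' Eigenvector values of a track
#' @param x a \linkS4class{CompartmentTrack}.
#' @export
eigenvector <- function(x) x@e1

#' Detect compartment switches between two sample groups
#'
#' A bin switches when every sample of group 1 carries one eigenvector sign
#' and every sample of group 2 the opposite sign (within-group unanimity).
#' Runs of at least \code{minRun} switching bins are merged into regions;
#' genes overlapping a region by at least 1 bp are reported.
#'
#' @param group1,group2 lists of oriented \linkS4class{CompartmentTrack}s on
#'   identical bins.
#' @param minRun minimum run length in bins (default 3).
#' @param genes optional \code{GRanges} or BED path of gene intervals.
#' @return list: \code{regions} (\code{GRanges} with a direction label, e.g.
#'   "A->B" for group1 A becoming group2 B), \code{bins} (logical per-bin
#'   switch indicator), \code{genes} (overlapping gene \code{GRanges} or
#'   NULL), \code{nGenes}.
#' @export
detectSwitches <- function(group1, group2, minRun = 3, genes = NULL) {
    stopifnot(length(group1) >= 1, length(group2) >= 1)
    bins <- group1[[1]]@bins
    allTracks <- c(group1, group2)
    for (t in allTracks)
        if (!identical(t@bins@chromNames, bins@chromNames) ||
            t@bins@binSize != bins@binSize)
            stop("all tracks must share the same bins")
    sgn <- function(tr) sign(tr@e1)
    s1 <- vapply(group1, sgn, numeric(nBins(bins)))
    s2 <- vapply(group2, sgn, numeric(nBins(bins)))
    s1 <- matrix(s1, nrow = nBins(bins))
    s2 <- matrix(s2, nrow = nBins(bins))
    unan <- function(m) {
        out <- rep(NA_real_, nrow(m))
        ok <- rowSums(is.na(m) | m == 0) == 0
        agree <- ok & apply(m, 1, function(v) all(v == v[1]))
        out[agree] <- m[agree, 1]
        out
    }
    u1 <- unan(s1); u2 <- unan(s2)
    switching <- !is.na(u1) & !is.na(u2) & u1 == -u2
    regions <- GenomicRanges::GRanges()
    bt <- binTable(bins)
    for (idx in chromBinIdx(bins)) {
        r <- rle(switching[idx])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values & r$lengths >= minRun
        for (k in which(keep)) {
            gi <- idx[starts[k]:ends[k]]
            dir <- sprintf("%s->%s", ifelse(u1[gi[1]] > 0, "A", "B"),
                           ifelse(u2[gi[1]] > 0, "A", "B"))
            gr <- GenomicRanges::GRanges(
                bt$chrom[gi[1]],
                IRanges::IRanges(start = bt$start[gi[1]] + 1,
                                 end = bt$end[gi[length(gi)]]),
                direction = dir)
            regions <- c(regions, gr)
        }
    }
    hit <- NULL; nGenes <- 0L
    if (!is.null(genes)) {
        if (is.character(genes)) genes <- rtracklayer::import(genes, format = "BED")
        if (length(regions)) {
            hit <- genes[unique(S4Vectors::queryHits(
                GenomicRanges::findOverlaps(genes, regions, minoverlap = 1L)))]
            nGenes <- length(hit)
        } else hit <- genes[0]
    }
    list(regions = regions, bins = switching, genes = hit, nGenes = nGenes)
}

#' @describeIn compartmentEigenvector display method
#' @param object a \linkS4class{CompartmentTrack}.
#' @export
setMethod("show", "CompartmentTrack", function(object) {
    cat(sprintf(
        "CompartmentTrack: %d bins (%d A, %d B, %d NA), %soriented\n",
        nBins(object@bins), sum(object@label == "A", na.rm = TRUE),
        sum(object@label == "B", na.rm = TRUE), sum(is.na(object@e1)),
        if (object@oriented) "" else "un"))
})
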
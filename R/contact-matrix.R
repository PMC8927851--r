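#' Bin valid pairs into a genome-wide contact matrix
#'
#' Each pair increments the cell (bin(pos1), bin(pos2)); the matrix is
#' symmetrized so both triangles are filled and the total over the upper
#' triangle (including the diagonal) equals the record count.
#'
#' @param pairs a \linkS4class{ValidPairSet}.
#' @param genome a \linkS4class{GenomeBins} (its chromosomes must cover the
#'   pairs) or a named vector of chromosome lengths.
#' @param B bin size in bp.
#' @return an unnormalized \linkS4class{ContactMatrix}.
#' @export
binContacts <- function(pairs, genome, B) {
    stopifnot(B > 0)
    bins <- if (is(genome, "GenomeBins")) genomeBins(
        setNames(genome@chromLengths, genome@chromNames), B)
        else genomeBins(genome, B)
    n <- nBins(bins)
    r <- pairs@records
    m <- matrix(0, n, n)
    if (nrow(r)) {
        i <- globalBin(bins, r$chr1, r$pos1)
        j <- globalBin(bins, r$chr2, r$pos2)
        lo <- pmin(i, j); hi <- pmax(i, j)
        tab <- table(factor(lo + (hi - 1) * n))  # linear index in upper triangle
        idx <- as.integer(names(tab))
        m[idx] <- as.numeric(tab)
        m <- m + t(m)
        diag(m) <- diag(m) / 2
    }
    new("ContactMatrix", bins = bins, mat = m,
        bias = rep(1, n), mask = rep(FALSE, n),
        state = "raw", totalPairs = as.numeric(nrow(r)))
}

#' Full genome-wide matrix of a ContactMatrix
#' @param x a \linkS4class{ContactMatrix}.
#' @export
contactMap <- function(x) x@mat

#' Cis block for one chromosome
#' @param x a \linkS4class{ContactMatrix}.
#' @param chrom chromosome name.
#' @export
cisMatrix <- function(x, chrom) {
    idx <- chromBinIdx(x@bins)[[chrom]]
    if (is.null(idx)) stop("unknown chromosome: ", chrom)
    x@mat[idx, idx, drop = FALSE]
}

#' Trans block between two chromosomes
#' @param x a \linkS4class{ContactMatrix}.
#' @param chrom1,chrom2 distinct chromosome names.
#' @export
transBlock <- function(x, chrom1, chrom2) {
    ci <- chromBinIdx(x@bins)
    x@mat[ci[[chrom1]], ci[[chrom2]], drop = FALSE]
}

#' ICE bias vector
#' @param x a \linkS4class{ContactMatrix}.
#' @export
biasVector <- function(x) x@bias

#' Masked (filtered) bins
#' @param x a \linkS4class{ContactMatrix}.
#' @return logical per-bin vector, TRUE where masked.
#' @export
maskedBins <- function(x) x@mask

#' Normalization state ("raw", "iced", "oe", "fastlo")
#' @param x a \linkS4class{ContactMatrix}.
#' @export
matrixState <- function(x) x@state

#' @describeIn binContacts display method
#' @param object a \linkS4class{ContactMatrix}.
#' @export
setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf(
        "ContactMatrix [%s]: %d bins @ %s bp, %s pairs, %d masked bin(s)\n",
        object@state, nBins(object@bins),
        format(object@bins@binSize, big.mark = ","),
        format(object@totalPairs, big.mark = ","), sum(object@mask)))
})

#' Export a contact matrix as triplet text plus a bins table
#'
#' Writes the upper triangle (including the diagonal) of non-zero cells as
#' zero-based \code{binID1\tbinID2\tvalue} triplets, and a four-column bins
#' table (chrom, start, end, binID) — the sparse interchange layout used by
#' standard Hi-C matrix tooling.
#'
#' @param x a \linkS4class{ContactMatrix}.
#' @param matrixPath,binsPath destinations.
#' @export
writeTripletMatrix <- function(x, matrixPath, binsPath) {
    m <- x@mat
    keep <- upper.tri(m, diag = TRUE) & !is.na(m) & m != 0
    idx <- which(keep, arr.ind = TRUE)
    dt <- data.table::data.table(bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                                 value = m[keep])
    data.table::setorder(dt, bin1, bin2)
    data.table::fwrite(dt, matrixPath, sep = "\t", col.names = FALSE)
    data.table::fwrite(binTable(x@bins), binsPath, sep = "\t", col.names = FALSE)
    invisible(matrixPath)
}

#' Read a triplet matrix written by \code{writeTripletMatrix}
#'
#' @param matrixPath,binsPath the triplet and bins files.
#' @param binSize bin size in bp (recovered from the bins table if omitted).
#' @return a raw-state \linkS4class{ContactMatrix} (bias 1, no mask).
#' @export
readTripletMatrix <- function(matrixPath, binsPath, binSize = NULL) {
    bt <- data.table::fread(binsPath, header = FALSE,
                            col.names = c("chrom", "start", "end", "binID"))
    if (is.null(binSize)) binSize <- max(bt$end - bt$start)
    lens <- tapply(bt$end, bt$chrom, max)
    # preserve file order of chromosomes
    ord <- unique(bt$chrom)
    bins <- genomeBins(setNames(as.numeric(lens[ord]), ord), binSize)
    trip <- data.table::fread(matrixPath, header = FALSE,
                              col.names = c("bin1", "bin2", "value"))
    n <- nBins(bins)
    m <- matrix(0, n, n)
    m[cbind(trip$bin1 + 1L, trip$bin2 + 1L)] <- trip$value
    m <- m + t(m)
    diag(m) <- diag(m) / 2
    new("ContactMatrix", bins = bins, mat = m, bias = rep(1, n),
        mask = rep(FALSE, n), state = "raw", totalPairs = sum(trip$value))
}

#' Cis/trans interaction summary
#'
#' Mean interaction per cis (per-chromosome) block and per trans
#' (chromosome-pair) block over unmasked cells, with flagging of trans blocks
#' whose mean exceeds \code{k} times the median trans mean — the screen used
#' to spot large rearrangements (a strengthened trans block between two
#' chromosome arms).
#'
#' @param x a \linkS4class{ContactMatrix} (raw or normalized; the state is
#'   recorded in the output).
#' @param k flagging multiplier (default 3).
#' @return list with \code{cis} (data.frame chrom, mean), \code{trans}
#'   (data.frame chrom1, chrom2, mean, flagged), \code{state}.
#' @export
cisTransSummary <- function(x, k = 3) {
    ci <- chromBinIdx(x@bins)
    keep <- !x@mask
    cis <- data.frame(chrom = x@bins@chromNames, mean = NA_real_)
    for (s in seq_along(ci)) {
        idx <- ci[[s]][keep[ci[[s]]]]
        if (length(idx)) cis$mean[s] <- mean(x@mat[idx, idx], na.rm = TRUE)
    }
    cn <- x@bins@chromNames
    tr <- NULL
    if (length(cn) > 1) {
        cmb <- utils::combn(cn, 2)
        tr <- data.frame(chrom1 = cmb[1, ], chrom2 = cmb[2, ], mean = NA_real_)
        for (r in seq_len(ncol(cmb))) {
            i1 <- ci[[cmb[1, r]]]; i1 <- i1[keep[i1]]
            i2 <- ci[[cmb[2, r]]]; i2 <- i2[keep[i2]]
            if (length(i1) && length(i2))
                tr$mean[r] <- mean(x@mat[i1, i2], na.rm = TRUE)
        }
        med <- median(tr$mean, na.rm = TRUE)
        tr$flagged <- !is.na(tr$mean) & med > 0 & tr$mean > k * med
    } else {
        tr <- data.frame(chrom1 = character(), chrom2 = character(),
                         mean = numeric(), flagged = logical())
    }
    list(cis = cis, trans = tr, state = x@state)
}

#' Delta matrix between two samples
#'
#' Scales both matrices to the same total contact sum (the mean of the two
#' totals over unmasked cells) and returns the elementwise difference A - B.
#' Cells masked in either input are NA.
#'
#' @param a,b \linkS4class{ContactMatrix} objects on identical bins and in the
#'   same normalization state.
#' @return a plain numeric matrix (signed).
#' @export
deltaMatrix <- function(a, b) {
    if (!identical(dim(a@mat), dim(b@mat)) ||
        !identical(a@bins@chromNames, b@bins@chromNames) ||
        a@bins@binSize != b@bins@binSize)
        stop("matrices must share the same binning scheme")
    if (a@state != b@state)
        stop("matrices must be in the same normalization state")
    mask <- a@mask | b@mask
    ma <- a@mat; mb <- b@mat
    ma[mask, ] <- NA; ma[, mask] <- NA
    mb[mask, ] <- NA; mb[, mask] <- NA
    sa <- sum(ma, na.rm = TRUE); sb <- sum(mb, na.rm = TRUE)
    if (sa == 0 || sb == 0) stop("cannot scale an all-zero matrix")
    tgt <- (sa + sb) / 2
    ma * (tgt / sa) - mb * (tgt / sb)
}
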
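#' Insulation score
#'
#' For each bin i, s_i is the mean contact value of the w x w square of cells
#' between the w bins upstream and the w bins downstream of i (unmasked cells
#' only; windows with more than half of their cells masked yield NA), defined
#' where the full window fits inside the chromosome. The reported score is
#' the log-ratio I_i = log2(s_i / chromosome mean of s), so it is invariant
#' to global matrix scaling and averages to unity on the natural scale.
#'
#' @param x a normalized \linkS4class{ContactMatrix} ("iced").
#' @param w window half-width in bins (default 25).
#' @param maxMaskedFrac NA threshold on the masked fraction of a window.
#' @return an \linkS4class{InsulationTrack}.
#' @export
insulationScore <- function(x, w = 25, maxMaskedFrac = 0.5) {
    if (!x@state %in% c("iced", "raw", "fastlo"))
        stop("insulation expects a contact (not O/E) matrix")
    w <- as.integer(w)
    stopifnot(w >= 1)
    n <- nBins(x@bins)
    s <- rep(NA_real_, n)
    for (ch in x@bins@chromNames) {
        idx <- chromBinIdx(x@bins)[[ch]]
        nc <- length(idx)
        if (nc < 2 * w + 1) {
            warning("chromosome ", ch, " shorter than 2w+1 bins; all NA")
            next
        }
        M <- maskedCisBlock(x, ch)
        for (i in (w + 1):(nc - w)) {
            if (x@mask[idx[i]]) next
            win <- M[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
            nOk <- sum(!is.na(win))
            if (nOk < (1 - maxMaskedFrac) * w * w) next
            s[idx[i]] <- mean(win, na.rm = TRUE)
        }
    }
    ins <- rep(NA_real_, n)
    for (idx in chromBinIdx(x@bins)) {
        def <- !is.na(s[idx])
        if (any(def)) {
            m <- mean(s[idx][def])
            if (m > 0) ins[idx][def] <- log2(s[idx][def] / m)
        }
    }
    new("InsulationTrack", bins = x@bins, window = w, raw = s,
        insulation = ins)
}

#' Insulation values of a track
#' @param x an \linkS4class{InsulationTrack}.
#' @export
insulationValues <- function(x) x@insulation

#' Call TAD boundaries and TADs from an insulation track
#'
#' Boundaries are local minima of the insulation score whose strength — the
#' mean of the two flanking local maxima minus the minimum value — reaches
#' \code{strengthMin}. TADs are the intervals between consecutive boundaries
#' (within each contiguous defined segment) of at least \code{minTad} bins.
#'
#' @param track an \linkS4class{InsulationTrack}.
#' @param strengthMin minimum boundary strength (default 0.1).
#' @param minTad minimum TAD size in bins (default 3).
#' @return list: \code{boundaries} (data.frame chrom, bin (1-based within
#'   chromosome), globalBin, pos (bp of bin start), strength),
#'   \code{tads} (data.frame chrom, startBin, endBin, start, end).
#' @export
callTads <- function(track, strengthMin = 0.1, minTad = 3) {
    bt <- binTable(track@bins)
    bnd <- NULL; tads <- NULL
    ci <- chromBinIdx(track@bins)
    for (ch in track@bins@chromNames) {
        idx <- ci[[ch]]
        I <- track@insulation[idx]
        def <- which(!is.na(I))
        if (!length(def)) next
        # process each contiguous run of defined scores
        segs <- split(def, cumsum(c(1, diff(def) != 1)))
        chBnd <- NULL
        for (seg in segs) {
            v <- I[seg]
            m <- length(v)
            if (m < 3) next
            dv <- diff(v)
            # local minima / maxima with plateau handling: use sign changes
            sgn <- sign(dv)
            nz <- sgn[sgn != 0]
            pos <- which(sgn != 0)
            if (length(nz) < 2) next
            turns <- which(nz[-1] != nz[-length(nz)])
            for (t in turns) {
                if (!(nz[t] == -1 && nz[t + 1] == 1)) next  # want min
                lo <- pos[t] + 1; hi <- pos[t + 1]
                cand <- lo:hi  # plateau of the minimum
                i0 <- cand[ceiling(length(cand) / 2)]
                # flanking local maxima: nearest peak walking out each side
                lmax <- localFlankMax(v, i0, -1L)
                rmax <- localFlankMax(v, i0, +1L)
                strength <- mean(c(lmax, rmax), na.rm = TRUE) - v[i0]
                if (is.finite(strength) && strength >= strengthMin)
                    chBnd <- rbind(chBnd, data.frame(
                        chrom = ch, bin = seg[i0], globalBin = idx[seg[i0]],
                        strength = strength))
            }
            if (!is.null(chBnd)) {
                inSeg <- chBnd$bin[chBnd$bin %in% seg]
                if (length(inSeg) >= 2) {
                    for (k in seq_len(length(inSeg) - 1)) {
                        a <- inSeg[k]; b <- inSeg[k + 1]
                        if (b - a >= minTad)
                            tads <- rbind(tads, data.frame(
                                chrom = ch, startBin = a, endBin = b,
                                start = bt$start[idx[a]], end = bt$end[idx[b]]))
                    }
                }
            }
        }
        if (!is.null(chBnd)) {
            chBnd$pos <- bt$start[chBnd$globalBin]
            bnd <- rbind(bnd, chBnd)
        }
    }
    if (is.null(bnd)) bnd <- data.frame(chrom = character(), bin = integer(),
                                        globalBin = integer(),
                                        strength = numeric(), pos = numeric())
    if (is.null(tads)) tads <- data.frame(chrom = character(),
                                          startBin = integer(),
                                          endBin = integer(),
                                          start = numeric(), end = numeric())
    list(boundaries = bnd, tads = tads)
}

# value of the nearest local maximum walking from i0 in direction dir
localFlankMax <- function(v, i0, dir) {
    i <- i0
    best <- -Inf
    while (TRUE) {
        nxt <- i + dir
        if (nxt < 1 || nxt > length(v)) break
        if (v[nxt] >= v[i]) { i <- nxt; best <- max(best, v[i]) }
        else if (best > -Inf) break else { i <- nxt }
    }
    if (best > -Inf) best else NA_real_
}

#' Insulation difference between two samples
#'
#' Per-bin difference of insulation scores (A - B); NA propagates. Used to
#' contrast boundary landscapes between samples (e.g. each sample against a
#' reference line).
#'
#' @param a,b \linkS4class{InsulationTrack}s on identical bins and window.
#' @return numeric per-bin difference.
#' @export
insulationDelta <- function(a, b) {
    if (!identical(a@bins@chromNames, b@bins@chromNames) ||
        a@bins@binSize != b@bins@binSize || a@window != b@window)
        stop("tracks must share bins and window")
    a@insulation - b@insulation
}

#' @describeIn insulationScore display method
#' @param object an \linkS4class{InsulationTrack}.
#' @export
setMethod("show", "InsulationTrack", function(object) {
    cat(sprintf("InsulationTrack: w=%d bins, %d/%d bins defined\n",
                object@window, sum(!is.na(object@insulation)),
                nBins(object@bins)))
})
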
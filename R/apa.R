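#' Aggregate peak analysis
#'
#' Averages the (2W+1) x (2W+1) observed/expected submatrices centered on a
#' set of anchor pixels. The APA score is the center value divided by the
#' mean of the c x c lower-left corner (the corner towards the diagonal).
#' Anchors whose window leaves the matrix, crosses the diagonal (distance
#' <= 2W) or covers masked bins at the center are skipped and counted.
#'
#' @param x a \linkS4class{ContactMatrix} in "oe" state.
#' @param anchors data.frame (chrom, i, j) of anchor bins (1-based per
#'   chromosome, i < j), e.g. loop calls of a reference sample.
#' @param W window half-width in bins (default 5).
#' @param corner corner size c in bins (default 3).
#' @return an \linkS4class{ApaResult}.
#' @export
apa <- function(x, anchors, W = 5, corner = 3) {
    if (x@state != "oe") stop("APA expects an observed/expected matrix")
    W <- as.integer(W); corner <- as.integer(corner)
    stopifnot(W >= 1, corner >= 1, corner <= 2 * W + 1)
    ci <- chromBinIdx(x@bins)
    acc <- matrix(0, 2 * W + 1, 2 * W + 1)
    cnt <- matrix(0, 2 * W + 1, 2 * W + 1)
    used <- 0L; skipped <- 0L
    for (k in seq_len(nrow(anchors))) {
        ch <- anchors$chrom[k]
        idx <- ci[[ch]]
        if (is.null(idx)) { skipped <- skipped + 1L; next }
        nc <- length(idx)
        i <- anchors$i[k]; j <- anchors$j[k]
        if (i - W < 1 || j + W > nc || j - i <= 2 * W ||
            x@mask[idx[i]] || x@mask[idx[j]]) { skipped <- skipped + 1L; next }
        sub <- x@mat[idx[(i - W):(i + W)], idx[(j - W):(j + W)]]
        ok <- !is.na(sub)
        acc[ok] <- acc[ok] + sub[ok]
        cnt <- cnt + ok
        used <- used + 1L
    }
    if (used == 0L) stop("no usable anchors for APA")
    agg <- acc / cnt
    centr <- agg[W + 1, W + 1]
    ll <- agg[(2 * W + 1 - corner + 1):(2 * W + 1), 1:corner]
    score <- centr / mean(ll, na.rm = TRUE)
    new("ApaResult", agg = agg, score = score, W = W, corner = corner,
        nAnchors = used, nSkipped = skipped,
        diff = matrix(numeric(0), 0, 0), scoreDiff = NA_real_)
}

#' APA difference to a reference sample
#'
#' Cellwise difference of two aggregates computed with the same window and
#' anchor list (sample minus reference), as used to contrast loop strength
#' across samples against one reference sample.
#'
#' @param x sample \linkS4class{ApaResult}.
#' @param reference reference \linkS4class{ApaResult}.
#' @return \code{x} with the \code{diff} matrix and \code{scoreDiff} filled.
#' @export
apaVsReference <- function(x, reference) {
    if (x@W != reference@W || x@corner != reference@corner)
        stop("APA results must share window and corner size")
    x@diff <- x@agg - reference@agg
    x@scoreDiff <- x@score - reference@score
    x
}

#' APA score
#' @param x an \linkS4class{ApaResult}.
#' @export
apaScore <- function(x) x@score

#' Pairs of consecutive TAD boundaries as APA-style anchors
#'
#' Builds anchor pixels from a boundary table (e.g. a reference sample's TAD
#' boundaries): every pair of boundaries on the same chromosome within the
#' distance band becomes one anchor pixel.
#'
#' @param boundaries data.frame with chrom and bin columns (as returned in
#'   \code{callTads()$boundaries}).
#' @param minSep,maxSep distance band in bins.
#' @export
boundaryAnchors <- function(boundaries, minSep = 11, maxSep = 100) {
    out <- NULL
    for (ch in unique(boundaries$chrom)) {
        b <- sort(boundaries$bin[boundaries$chrom == ch])
        if (length(b) < 2) next
        cmb <- utils::combn(b, 2)
        sep <- cmb[2, ] - cmb[1, ]
        keep <- sep >= minSep & sep <= maxSep
        if (any(keep))
            out <- rbind(out, data.frame(chrom = ch, i = cmb[1, keep],
                                         j = cmb[2, keep]))
    }
    if (is.null(out)) data.frame(chrom = character(), i = integer(),
                                 j = integer()) else out
}

#' @describeIn apa display method
#' @param object an \linkS4class{ApaResult}.
#' @export
setMethod("show", "ApaResult", function(object) {
    cat(sprintf("ApaResult: W=%d, %d anchor(s) (%d skipped), score %.3f%s\n",
                object@W, object@nAnchors, object@nSkipped, object@score,
                if (is.na(object@scoreDiff)) ""
                else sprintf(", score diff to reference %+.3f",
                             object@scoreDiff)))
})
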
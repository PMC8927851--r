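#' 2D mean filter
#'
#' Replaces each cell by the mean of all cells within Chebyshev radius h,
#' clipped at the matrix bounds; h = 0 is the identity. This is the
#' smoothing step of the stratum-adjusted correlation.
#'
#' @param m numeric matrix.
#' @param h half-width in cells.
#' @return smoothed matrix of the same dimension.
#' @export
smoothMeanFilter <- function(m, h) {
    stopifnot(h >= 0)
    h <- as.integer(h)
    if (h == 0L) return(m)
    nr <- nrow(m); nc <- ncol(m)
    # summed-area table with zero padding
    S <- matrix(0, nr + 1, nc + 1)
    cs <- apply(m, 2, cumsum)          # cumulative over rows
    S[-1, -1] <- t(apply(cs, 1, cumsum))  # then over columns
    r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
    c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
    out <- (S[cbind(rep(r2 + 1, nc), rep(c2 + 1, each = nr))] -
            S[cbind(rep(r1, nc),     rep(c2 + 1, each = nr))] -
            S[cbind(rep(r2 + 1, nc), rep(c1, each = nr))] +
            S[cbind(rep(r1, nc),     rep(c1, each = nr))])
    area <- (rep(r2, nc) - rep(r1, nc) + 1) * (rep(c2, each = nr) -
                                               rep(c1, each = nr) + 1)
    matrix(out / area, nr, nc)
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' Reproducibility measure between two contact maps: both are smoothed with a
#' 2D mean filter of half-width h, cis cells are stratified by genomic
#' distance up to D, and the per-stratum Pearson correlations r_d are
#' combined with weights w_d = N_d * sd(x_d) * sd(y_d). Zero-variance strata
#' are skipped. Reported per chromosome and genome-wide (strata pooled across
#' chromosomes in the weighted average).
#'
#' @param a,b \linkS4class{ContactMatrix} objects on identical bins, both raw
#'   or both in the same normalized state.
#' @param h smoothing half-width in bins (default 2).
#' @param maxDist maximum distance D in bp (default 5e6).
#' @return an \linkS4class{SccResult}.
#' @export
scc <- function(a, b, h = 2, maxDist = 5e6) {
    if (!identical(a@bins@chromNames, b@bins@chromNames) ||
        a@bins@binSize != b@bins@binSize)
        stop("matrices must share the same bins")
    if (a@state != b@state)
        stop("matrices must be in the same normalization state")
    B <- a@bins@binSize
    dmaxBins <- floor(maxDist / B)
    strata <- NULL
    ci <- chromBinIdx(a@bins)
    for (ch in a@bins@chromNames) {
        idx <- ci[[ch]]
        nc <- length(idx)
        X <- smoothMeanFilter(a@mat[idx, idx], h)
        Y <- smoothMeanFilter(b@mat[idx, idx], h)
        for (d in seq_len(min(dmaxBins, nc - 1))) {
            sel <- cbind(seq_len(nc - d), seq_len(nc - d) + d)
            x <- X[sel]; y <- Y[sel]
            ok <- !is.na(x) & !is.na(y)
            x <- x[ok]; y <- y[ok]
            if (length(x) < 3) next
            sx <- sd(x); sy <- sd(y)
            if (sx == 0 || sy == 0) next
            strata <- rbind(strata, data.frame(
                chrom = ch, distance = d * B, r = cor(x, y),
                n = length(x), w = length(x) * sx * sy))
        }
    }
    if (is.null(strata)) stop("no usable distance strata for SCC")
    perChrom <- vapply(split(strata, strata$chrom), function(s)
        sum(s$w * s$r) / sum(s$w), numeric(1))
    new("SccResult", scc = sum(strata$w * strata$r) / sum(strata$w),
        perChrom = perChrom, strata = strata, h = as.integer(h),
        maxDist = maxDist)
}

#' Genome-wide SCC value
#' @param x an \linkS4class{SccResult}.
#' @export
sccValue <- function(x) x@scc

#' Pairwise SCC matrix over a list of samples
#'
#' @param mats named list of \linkS4class{ContactMatrix} objects.
#' @param h,maxDist see \code{\link{scc}}.
#' @return symmetric numeric matrix of genome-wide SCC values (1 on the
#'   diagonal).
#' @export
sccMatrix <- function(mats, h = 2, maxDist = 5e6) {
    n <- length(mats)
    out <- diag(1, n)
    dimnames(out) <- list(names(mats), names(mats))
    if (n < 2) return(out)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        v <- sccValue(scc(mats[[i]], mats[[j]], h = h, maxDist = maxDist))
        out[i, j] <- v; out[j, i] <- v
    }
    out
}

#' @describeIn scc display method
#' @param object an \linkS4class{SccResult}.
#' @export
setMethod("show", "SccResult", function(object) {
    cat(sprintf("SccResult: SCC = %.4f (h=%d, D<=%s bp, %d strata)\n",
                object@scc, object@h,
                format(object@maxDist, big.mark = ","), nrow(object@strata)))
})
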
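#' ICE matrix balancing (iterative correction)
#'
#' Masks the lowest-coverage fraction of bins, then iteratively divides each
#' row and column by its relative coverage s_i / mean(s) until the row sums of
#' unmasked bins agree to within \code{eps} (max relative deviation from their
#' mean) or \code{maxIter} is reached. The accumulated divisor per bin is the
#' bias vector b_i, so raw = balanced * b_i * b_j.
#'
#' Defaults follow the standard Hi-C processing configuration:
#' \code{maxIter = 100}, \code{lowPct = 0.02}, \code{highPct = 0},
#' \code{eps = 0.1}.
#'
#' @param x a raw-state \linkS4class{ContactMatrix}.
#' @param maxIter maximum number of correction iterations.
#' @param lowPct fraction of bins with lowest total coverage to mask
#'   (zero-coverage bins are always masked).
#' @param highPct fraction of highest-coverage bins to mask.
#' @param eps convergence tolerance on max |s_i/mean(s) - 1|.
#' @return a \linkS4class{ContactMatrix} with state "iced", the bias vector
#'   filled (NA on masked bins) and masked rows/columns zeroed.
#' @export
iceNormalize <- function(x, maxIter = 100, lowPct = 0.02, highPct = 0,
                         eps = 0.1) {
    if (x@state != "raw")
        stop("iceNormalize expects an unnormalized (raw) matrix")
    m <- x@mat
    n <- nrow(m)
    if (sum(m) == 0) stop("nothing to balance: all-zero matrix")
    cov <- rowSums(m)
    mask <- cov == 0
    if (lowPct > 0) {
        k <- floor(lowPct * n)
        if (k > 0) mask[order(cov)[seq_len(k)]] <- TRUE
    }
    if (highPct > 0) {
        k <- floor(highPct * n)
        if (k > 0) mask[order(cov, decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
    if (all(mask)) stop("nothing to balance: every bin masked")
    m[mask, ] <- 0
    m[, mask] <- 0
    bias <- rep(1, n)
    u <- which(!mask)
    for (it in seq_len(maxIter)) {
        s <- rowSums(m[u, , drop = FALSE])
        if (any(s == 0)) {  # bins emptied by masking drop out of the balance
            newly <- u[s == 0]
            mask[newly] <- TRUE
            u <- which(!mask)
            if (!length(u)) stop("nothing to balance: every bin masked")
            s <- s[s > 0]
        }
        rel <- s / mean(s)
        if (max(abs(rel - 1)) < eps) break
        m[u, ] <- m[u, ] / rel
        m[, u] <- sweep(m[, u, drop = FALSE], 2, rel, "/")
        bias[u] <- bias[u] * rel
    }
    bias[mask] <- NA_real_
    new("ContactMatrix", bins = x@bins, mat = m, bias = bias, mask = mask,
        state = "iced", totalPairs = x@totalPairs)
}
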
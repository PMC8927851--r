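# shared cis upper-triangle pixel frame for a list of matrices on equal bins:
# chrom, i, j (per-chromosome bins), distance (bp), one IF column per sample
pixelFrame <- function(mats) {
    bins <- mats[[1]]@bins
    for (m in mats)
        if (!identical(m@bins@chromNames, bins@chromNames) ||
            m@bins@binSize != bins@binSize)
            stop("all matrices must share the same bins")
    mask <- Reduce("|", lapply(mats, maskedBins))
    ci <- chromBinIdx(bins)
    out <- NULL
    for (ch in bins@chromNames) {
        idx <- ci[[ch]]
        nc <- length(idx)
        ut <- which(upper.tri(matrix(0, nc, nc), diag = TRUE), arr.ind = TRUE)
        keep <- !mask[idx[ut[, 1]]] & !mask[idx[ut[, 2]]]
        ut <- ut[keep, , drop = FALSE]
        df <- data.frame(chrom = ch, i = ut[, 1], j = ut[, 2],
                         distance = (ut[, 2] - ut[, 1]) * bins@binSize)
        for (s in seq_along(mats))
            df[[paste0("IF", s)]] <-
                mats[[s]]@mat[idx, idx][cbind(ut[, 1], ut[, 2])]
        out <- rbind(out, df)
    }
    out
}

#' Joint fast-loess normalization of a set of contact matrices
#'
#' Cyclic loess on interaction frequencies against genomic distance: per
#' cycle and sample, M = log2(IF + 0.5) minus the across-sample mean is
#' regressed on distance with LOWESS and the fitted trend subtracted, which
#' removes sample-specific distance-dependent biases. Matrix totals are then
#' rescaled to the mean of the original totals so depths are comparable.
#'
#' @param mats list of \linkS4class{ContactMatrix} objects on identical bins.
#' @param span LOWESS span (default 0.3).
#' @param cycles number of cycles (default 3).
#' @return list of \linkS4class{ContactMatrix} objects with state "fastlo".
#' @export
jointNormalize <- function(mats, span = 0.3, cycles = 3) {
    if (length(mats) < 2) stop("joint normalization needs at least 2 matrices")
    px <- pixelFrame(mats)
    S <- length(mats)
    P <- as.matrix(px[, paste0("IF", seq_len(S))])
    tot0 <- colSums(P)
    # log distance: the scale on which distance-dependent biases are smooth
    d <- log(px$distance + mats[[1]]@bins@binSize)
    ord <- order(d)
    for (cy in seq_len(cycles)) {
        A <- log2(P + 0.5)
        ctr <- rowMeans(A)
        for (s in seq_len(S)) {
            M <- A[, s] - ctr
            fit <- lowess(d[ord], M[ord], f = span, iter = 2)
            trend <- approx(fit$x, fit$y, xout = d, rule = 2, ties = mean)$y
            P[, s] <- pmax(2^(A[, s] - trend) - 0.5, 0)
        }
    }
    P <- sweep(P, 2, colSums(P), "/") * mean(tot0)
    bins <- mats[[1]]@bins
    ci <- chromBinIdx(bins)
    lapply(seq_len(S), function(s) {
        m <- mats[[s]]
        out <- m@mat
        for (ch in bins@chromNames) {
            idx <- ci[[ch]]
            sel <- px$chrom == ch
            out[idx, idx][cbind(px$i[sel], px$j[sel])] <- P[sel, s]
            out[idx, idx][cbind(px$j[sel], px$i[sel])] <- P[sel, s]
        }
        new("ContactMatrix", bins = bins, mat = out, bias = m@bias,
            mask = Reduce("|", lapply(mats, maskedBins)), state = "fastlo",
            totalPairs = m@totalPairs)
    })
}

# conditional two-group exact test on group sums y1 + y2 = Tt with n1 and n2
# samples; negative binomial with dispersion phi, reducing to a binomial
# split when phi ~ 0; two-sided by summing outcome probabilities <= observed
exactTestPixel <- function(y1, Tt, n1, n2, phi) {
    if (Tt == 0) return(1)
    k <- 0:Tt
    if (phi < 1e-8) {
        pr <- dbinom(k, Tt, n1 / (n1 + n2))
    } else {
        mu <- Tt / (n1 + n2)
        pr <- dnbinom(k, size = n1 / phi, mu = n1 * mu) *
            dnbinom(Tt - k, size = n2 / phi, mu = n2 * mu)
        s <- sum(pr)
        if (s == 0) return(1)
        pr <- pr / s
    }
    p <- sum(pr[pr <= pr[y1 + 1] * (1 + 1e-7)])
    if (p > 1 - 1e-9) 1 else p
}

#' Exact-test differential interaction detection between two groups
#'
#' For every cis pixel of jointly normalized matrices, rounds the normalized
#' interaction frequencies to counts, estimates a per-distance-stratum
#' dispersion by the method of moments across all samples, and applies a
#' conditional two-group exact test (negative binomial; a binomial split of
#' the pixel total when the dispersion vanishes), followed by BH adjustment
#' across tested pixels. Pixels with zero total are excluded.
#'
#' @param mats list of \linkS4class{ContactMatrix} objects, jointly
#'   normalized (state "fastlo"; other states are accepted with a warning).
#' @param groups character/factor of length \code{length(mats)} with exactly
#'   two levels.
#' @param stratumBp width of the dispersion-estimation distance strata
#'   (default 10 bins' worth, computed from the bin size).
#' @return a DiffTable data.frame: chrom, i, j, distance, mean IF per group,
#'   M (log2 group2/group1), p, q.
#' @export
exactTestDiff <- function(mats, groups, stratumBp = NULL) {
    stopifnot(length(groups) == length(mats))
    groups <- factor(groups, levels = unique(as.character(groups)))
    if (nlevels(groups) != 2) stop("exactly two groups required")
    if (any(vapply(mats, matrixState, "") != "fastlo"))
        warning("matrices are not jointly normalized; run jointNormalize first")
    bins <- mats[[1]]@bins
    if (is.null(stratumBp)) stratumBp <- 10 * bins@binSize
    px <- pixelFrame(mats)
    S <- length(mats)
    C <- round(as.matrix(px[, paste0("IF", seq_len(S))]))
    tot <- rowSums(C)
    keep <- tot > 0
    px <- px[keep, , drop = FALSE]
    C <- C[keep, , drop = FALSE]
    g1 <- which(groups == levels(groups)[1])
    g2 <- which(groups == levels(groups)[2])
    n1 <- length(g1); n2 <- length(g2)
    y1 <- rowSums(C[, g1, drop = FALSE])
    y2 <- rowSums(C[, g2, drop = FALSE])
    mu <- rowMeans(C)
    v <- apply(C, 1, stats::var)
    stratum <- pmax(1, ceiling(px$distance / stratumBp))
    phiTab <- vapply(split(seq_len(nrow(px)), stratum), function(ii) {
        num <- sum(v[ii] - mu[ii])
        den <- sum(mu[ii]^2)
        if (den > 0) max(0, num / den) else 0
    }, numeric(1))
    phi <- phiTab[as.character(stratum)]
    Tt <- y1 + y2
    # identical test statistics share one p-value computation
    key <- paste(y1, Tt, signif(phi, 3), sep = ":")
    uk <- !duplicated(key)
    pv <- setNames(mapply(function(a, b, f) exactTestPixel(a, b, n1, n2, f),
                          y1[uk], Tt[uk], phi[uk]), key[uk])
    p <- unname(pv[key])
    m1 <- y1 / n1; m2 <- y2 / n2
    out <- data.frame(chrom = px$chrom, i = px$i, j = px$j,
                      distance = px$distance,
                      mean1 = m1, mean2 = m2,
                      M = ifelse(m1 > 0 & m2 > 0, log2(m2 / m1), NA),
                      p = p, q = p.adjust(p, "BH"))
    attr(out, "groups") <- levels(groups)
    out
}

#' Export a DiffTable as TSV
#'
#' Columns chrom, start1, start2, D, M, p, q — the flat layout used for
#' MD-composite plotting (M versus distance with a significance flag).
#'
#' @param diffTable result of \code{\link{exactTestDiff}}.
#' @param bins the \linkS4class{GenomeBins} used.
#' @param path destination.
#' @param qSig significance flag threshold (default 0.05).
#' @export
writeDiffTable <- function(diffTable, bins, path, qSig = 0.05) {
    B <- bins@binSize
    out <- data.frame(chrom = diffTable$chrom,
                      start1 = (diffTable$i - 1) * B,
                      start2 = (diffTable$j - 1) * B,
                      D = diffTable$distance, M = diffTable$M,
                      p = diffTable$p, q = diffTable$q,
                      significant = !is.na(diffTable$q) & diffTable$q < qSig)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}
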
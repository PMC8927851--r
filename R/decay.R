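# per-bin-distance sums and non-NA cell counts of a square (cis) block;
# masked cells must already be NA
perDistanceStats <- function(M) {
    nc <- nrow(M)
    d <- 0:(nc - 1)
    s <- numeric(nc); cnt <- numeric(nc)
    for (k in d) {
        v <- M[cbind(seq_len(nc - k), seq_len(nc - k) + k)]
        s[k + 1] <- sum(v, na.rm = TRUE)
        cnt[k + 1] <- sum(!is.na(v))
    }
    data.frame(d = d, sum = s, count = cnt)
}

# cis block with masked rows/columns set NA
maskedCisBlock <- function(x, chrom) {
    idx <- chromBinIdx(x@bins)[[chrom]]
    M <- x@mat[idx, idx, drop = FALSE]
    bad <- x@mask[idx]
    M[bad, ] <- NA
    M[, bad] <- NA
    M
}

#' Distance-decay (Ps) curve
#'
#' Mean contact value per genomic-distance stratum over all unmasked cis cell
#' pairs, per chromosome and genome-wide (chrom \code{".genome"}). The default
#' stratum width of 1 Mb matches the standard contact-probability analysis;
#' use \code{stratumBp = binSize(x)} for a per-bin-distance curve (as needed
#' by the observed/expected transform). The diagonal forms its own stratum at
#' distance 0. Per-chromosome RCP values are the observed means over strata at
#' positive distance, normalized to unit sum.
#'
#' @param x a \linkS4class{ContactMatrix} (any state).
#' @param stratumBp stratum width in bp (default 1e6).
#' @return a \linkS4class{DecayCurve} with the expected column unfilled (NA).
#' @export
decayCurve <- function(x, stratumBp = 1e6) {
    B <- x@bins@binSize
    rows <- list()
    pooled <- new.env()
    for (ch in x@bins@chromNames) {
        st <- perDistanceStats(maskedCisBlock(x, ch))
        stratum <- ifelse(st$d == 0, 0, ceiling(st$d * B / stratumBp))
        agg <- rowsum(cbind(st$sum, st$count), stratum)
        s <- as.numeric(rownames(agg))
        key <- as.character(s)
        for (k in seq_along(s)) {
            cur <- if (is.null(pooled[[key[k]]])) c(0, 0) else pooled[[key[k]]]
            pooled[[key[k]]] <- cur + agg[k, ]
        }
        rows[[ch]] <- data.frame(chrom = ch, stratum = s,
                                 distance = s * stratumBp,
                                 observed = ifelse(agg[, 2] > 0,
                                                   agg[, 1] / agg[, 2], NA),
                                 n = agg[, 2])
    }
    ks <- sort(as.numeric(ls(pooled)))
    gw <- do.call(rbind, lapply(ks, function(s) {
        v <- pooled[[as.character(s)]]
        data.frame(chrom = ".genome", stratum = s, distance = s * stratumBp,
                   observed = if (v[2] > 0) v[1] / v[2] else NA, n = v[2])
    }))
    tab <- rbind(do.call(rbind, rows), gw)
    rownames(tab) <- NULL
    tab$expected <- NA_real_
    tab$rcp <- NA_real_
    for (ch in unique(tab$chrom)) {
        sel <- tab$chrom == ch & tab$stratum > 0 & tab$n > 0
        tot <- sum(tab$observed[sel])
        if (tot > 0) tab$rcp[sel] <- tab$observed[sel] / tot
    }
    new("DecayCurve", table = tab, stratumBp = stratumBp, binSize = B,
        f = NA_real_)
}

#' Fit the LOWESS expected model of a decay curve
#'
#' Locally weighted linear regression of log(observed) on log(distance),
#' evaluated at each stratum; fitting in log-log space keeps the expected
#' values strictly positive. With fewer than four usable strata the observed
#' values are used as expected, with a warning.
#'
#' @param curve a \linkS4class{DecayCurve}.
#' @param f LOWESS smoother span (default 0.3).
#' @param iter robustifying iterations (default 2).
#' @return the curve with its expected column filled.
#' @export
lowessExpected <- function(curve, f = 0.3, iter = 2) {
    tab <- curve@table
    for (ch in unique(tab$chrom)) {
        sel <- which(tab$chrom == ch & tab$stratum > 0 & tab$n > 0 &
                     !is.na(tab$observed) & tab$observed > 0)
        if (length(sel) < 4) {
            warning("fewer than 4 usable strata for ", ch,
                    "; using observed values as expected")
            tab$expected[sel] <- tab$observed[sel]
            next
        }
        lx <- log(tab$distance[sel]); ly <- log(tab$observed[sel])
        fit <- lowess(lx, ly, f = f, iter = iter)
        tab$expected[sel] <- exp(approx(fit$x, fit$y, xout = lx, rule = 2,
                                        ties = mean)$y)
        # strata observed at zero still need a (positive) expected value
        z <- which(tab$chrom == ch & tab$stratum > 0 & tab$n > 0 &
                   !(seq_len(nrow(tab)) %in% sel))
        if (length(z))
            tab$expected[z] <- exp(approx(fit$x, fit$y,
                                          xout = log(tab$distance[z]),
                                          rule = 2, ties = mean)$y)
    }
    d0 <- tab$stratum == 0 & tab$n > 0
    tab$expected[d0] <- tab$observed[d0]
    new("DecayCurve", table = tab, stratumBp = curve@stratumBp,
        binSize = curve@binSize, f = f)
}

#' Observed/expected transform of a contact matrix
#'
#' Divides each cis cell by the expected value at its genomic distance. If no
#' curve is supplied, a per-bin-distance curve is computed from the matrix
#' itself and its observed stratum means serve as expected (the classical
#' mean-at-distance convention); pass a \code{\link{lowessExpected}} curve for
#' the smoothed model. Masked cells and cells with zero expected are NA, as
#' are all trans cells.
#'
#' @param x a \linkS4class{ContactMatrix} (typically ICE-balanced).
#' @param curve optional \linkS4class{DecayCurve}.
#' @return a \linkS4class{ContactMatrix} with state "oe".
#' @export
observedOverExpected <- function(x, curve = NULL) {
    B <- x@bins@binSize
    if (is.null(curve)) curve <- decayCurve(x, stratumBp = B)
    tab <- curve@table
    n <- nBins(x@bins)
    out <- matrix(NA_real_, n, n)
    ci <- chromBinIdx(x@bins)
    for (ch in x@bins@chromNames) {
        idx <- ci[[ch]]
        nc <- length(idx)
        rows <- tab[tab$chrom == ch, ]
        if (!nrow(rows)) rows <- tab[tab$chrom == ".genome", ]
        ev <- rows$expected
        if (all(is.na(ev))) ev <- rows$observed
        lookup <- setNames(ev, rows$stratum)
        d <- abs(outer(seq_len(nc), seq_len(nc), "-"))
        stratum <- ifelse(d == 0, 0, ceiling(d * B / curve@stratumBp))
        e <- matrix(lookup[as.character(stratum)], nc, nc)
        blk <- x@mat[idx, idx] / e
        blk[!is.finite(blk)] <- NA
        bad <- x@mask[idx]
        blk[bad, ] <- NA
        blk[, bad] <- NA
        out[idx, idx] <- blk
    }
    new("ContactMatrix", bins = x@bins, mat = out, bias = x@bias,
        mask = x@mask, state = "oe", totalPairs = x@totalPairs)
}

#' Export decay curves as TSV
#' @param curve a \linkS4class{DecayCurve}.
#' @param path destination (columns chrom, distance, observed, expected, rcp, n).
#' @export
writeDecayCurve <- function(curve, path) {
    data.table::fwrite(
        curve@table[, c("chrom", "distance", "observed", "expected", "rcp", "n")],
        path, sep = "\t")
    invisible(path)
}

#' @describeIn decayCurve display method
#' @param object a \linkS4class{DecayCurve}.
#' @export
setMethod("show", "DecayCurve", function(object) {
    cat(sprintf("DecayCurve: %d strata of %s bp, %d chromosome track(s)%s\n",
                length(unique(object@table$stratum)),
                format(object@stratumBp, big.mark = ","),
                length(unique(object@table$chrom)) - 1L,
                if (is.na(object@f)) " (expected not fitted)"
                else sprintf(", LOWESS f=%.2f", object@f)))
})
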
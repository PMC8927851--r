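#' Call chromatin loops by local-neighborhood enrichment
#'
#' Simplified single-resolution HiCCUPS: every candidate cis pixel within the
#' distance band is compared against four local neighborhoods — donut,
#' lower-left, horizontal and vertical — on the balanced matrix. For each
#' neighborhood, the local expected value is
#' lambda = (neighborhood observed / neighborhood expected) x pixel expected
#' on the balanced scale, mapped back to raw-count scale through the ICE
#' biases for an upper-tail Poisson test. p-values are BH-adjusted across all
#' tested pixels (per neighborhood); a loop pixel must pass the q threshold
#' for donut and lower-left and the fold threshold against all four
#' neighborhoods. Touching significant pixels (8-connectivity) are clustered
#' and the most enriched pixel of each cluster is flagged as the centroid.
#'
#' @param x an ICE-balanced \linkS4class{ContactMatrix}.
#' @param curve optional \linkS4class{DecayCurve} for the expected model; by
#'   default a per-bin-distance mean-at-distance curve from \code{x}.
#' @param dMin minimum pixel distance in bins (default 2).
#' @param dMax maximum pixel distance in bp (default 2e6).
#' @param donutR outer neighborhood radius in bins (default 5).
#' @param innerR inner exclusion radius (default 2).
#' @param foldMin minimum fold enrichment over every neighborhood (1.5).
#' @param qMax BH q-value threshold for donut and lower-left (0.1).
#' @return a \linkS4class{LoopSet}.
#' @export
callLoops <- function(x, curve = NULL, dMin = 2, dMax = 2e6,
                      donutR = 5, innerR = 2, foldMin = 1.5, qMax = 0.1) {
    if (x@state != "iced")
        stop("loop calling requires an ICE-balanced matrix; run iceNormalize first")
    B <- x@bins@binSize
    if (is.null(curve)) curve <- decayCurve(x, stratumBp = B)
    tab <- curve@table
    R <- donutR; r <- innerR
    off <- expand.grid(di = -R:R, dj = -R:R)
    cheb <- pmax(abs(off$di), abs(off$dj))
    nb <- list(
        donut = off[cheb > r & cheb <= R & off$di != 0 & off$dj != 0, ],
        lowerLeft = off[off$di >= 1 & off$di <= R & off$dj <= -1 &
                        off$dj >= -R & cheb > r, ],
        horizontal = off[off$di == 0 & abs(off$dj) > r, ],
        vertical = off[off$dj == 0 & abs(off$di) > r, ])
    allPix <- NULL
    ci <- chromBinIdx(x@bins)
    for (ch in x@bins@chromNames) {
        idx <- ci[[ch]]
        nc <- length(idx)
        M <- x@mat[idx, idx]
        bad <- x@mask[idx]
        W <- matrix(1, nc, nc); W[bad, ] <- 0; W[, bad] <- 0
        Mm <- M * W
        rows <- tab[tab$chrom == ch, ]
        ev <- rows$expected
        if (all(is.na(ev))) ev <- rows$observed
        lookup <- setNames(ev, rows$stratum)
        dmat <- abs(outer(seq_len(nc), seq_len(nc), "-"))
        stratum <- ifelse(dmat == 0, 0, ceiling(dmat * B / curve@stratumBp))
        E <- matrix(lookup[as.character(stratum)], nc, nc)
        E[is.na(E)] <- 0
        Em <- E * W
        dmaxBins <- floor(dMax / B)
        cand <- which(dmat >= dMin & dmat <= dmaxBins &
                      upper.tri(dmat) & W > 0, arr.ind = TRUE)
        if (!nrow(cand)) next
        ii <- cand[, 1]; jj <- cand[, 2]
        m <- length(ii)
        stats <- lapply(nb, function(o) {
            sN <- numeric(m); sE <- numeric(m)
            for (k in seq_len(nrow(o))) {
                a <- ii + o$di[k]; b <- jj + o$dj[k]
                ok <- a >= 1 & a <= nc & b >= 1 & b <= nc & a != b
                sN[ok] <- sN[ok] + Mm[cbind(a[ok], b[ok])]
                sE[ok] <- sE[ok] + Em[cbind(a[ok], b[ok])]
            }
            list(sN = sN, sE = sE)
        })
        pix <- data.frame(chrom = ch, i = ii, j = jj, distance = (jj - ii) * B,
                          value = M[cbind(ii, jj)])
        bias <- x@bias[idx]
        bibj <- bias[ii] * bias[jj]
        rawCount <- round(pix$value * bibj)
        pexp <- E[cbind(ii, jj)]
        for (nm in names(nb)) {
            s <- stats[[nm]]
            lam <- ifelse(s$sE > 0, s$sN / s$sE * pexp, NA)
            pix[[paste0("fold_", nm)]] <- pix$value / lam
            lamRaw <- lam * bibj
            pix[[paste0("p_", nm)]] <-
                ifelse(is.na(lamRaw), 1,
                       ppois(rawCount - 1, lamRaw, lower.tail = FALSE))
        }
        allPix <- rbind(allPix, pix)
    }
    params <- list(dMin = dMin, dMax = dMax, donutR = donutR, innerR = innerR,
                   foldMin = foldMin, qMax = qMax)
    if (is.null(allPix))
        return(new("LoopSet", pixels = data.frame(), nTested = 0L,
                   params = params))
    allPix$q_donut <- p.adjust(allPix$p_donut, "BH")
    allPix$q_lowerLeft <- p.adjust(allPix$p_lowerLeft, "BH")
    sig <- allPix$q_donut <= qMax & allPix$q_lowerLeft <= qMax &
        allPix$fold_donut >= foldMin & allPix$fold_lowerLeft >= foldMin &
        allPix$fold_horizontal >= foldMin & allPix$fold_vertical >= foldMin
    sig[is.na(sig)] <- FALSE
    hits <- allPix[sig, , drop = FALSE]
    if (nrow(hits)) {
        hits <- clusterPixels(hits)
    } else {
        hits$cluster <- integer(); hits$centroid <- logical()
    }
    new("LoopSet", pixels = hits, nTested = nrow(allPix), params = params)
}

# single-linkage clustering of pixels touching within Chebyshev distance 1;
# the most donut-enriched pixel of each cluster is the centroid
clusterPixels <- function(hits) {
    n <- nrow(hits)
    cl <- seq_len(n)
    find <- function(a) { while (cl[a] != a) a <- cl[a]; a }
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
        if (hits$chrom[a] == hits$chrom[b] &&
            abs(hits$i[a] - hits$i[b]) <= 1 && abs(hits$j[a] - hits$j[b]) <= 1) {
            ra <- find(a); rb <- find(b)
            if (ra != rb) cl[ra] <- rb
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    hits$cluster <- as.integer(factor(root))
    hits$centroid <- FALSE
    for (g in split(seq_len(n), hits$cluster))
        hits$centroid[g[which.max(hits$fold_donut[g])]] <- TRUE
    hits
}

#' Reported loops (cluster centroids) of a LoopSet
#' @param x a \linkS4class{LoopSet}.
#' @export
loopPixels <- function(x) {
    if (!nrow(x@pixels)) return(x@pixels)
    x@pixels[x@pixels$centroid, , drop = FALSE]
}

#' Export loops as BEDPE
#'
#' @param x a \linkS4class{LoopSet}.
#' @param bins the \linkS4class{GenomeBins} the loops were called on.
#' @param path destination.
#' @export
writeLoopsBedpe <- function(x, bins, path) {
    lp <- loopPixels(x)
    con <- file(path, "w")
    writeLines("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\tscore", con)
    if (nrow(lp)) {
        B <- bins@binSize
        bt <- binTable(bins)
        ci <- chromBinIdx(bins)
        for (k in seq_len(nrow(lp))) {
            g1 <- ci[[lp$chrom[k]]][lp$i[k]]
            g2 <- ci[[lp$chrom[k]]][lp$j[k]]
            writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tloop%d\t%.3f",
                lp$chrom[k], as.integer(bt$start[g1]), as.integer(bt$end[g1]),
                lp$chrom[k], as.integer(bt$start[g2]), as.integer(bt$end[g2]),
                k, lp$fold_donut[k]), con)
        }
    }
    close(con)
    invisible(path)
}

#' @describeIn callLoops display method
#' @param object a \linkS4class{LoopSet}.
#' @export
setMethod("show", "LoopSet", function(object) {
    cat(sprintf("LoopSet: %d loop(s) from %d significant pixel(s), %d tested\n",
                nrow(loopPixels(object)), nrow(object@pixels),
                object@nTested))
})
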
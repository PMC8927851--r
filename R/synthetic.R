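# run expr with a local, restored RNG state so generators never leak
# global RNG side effects
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Evenly spaced interior TAD boundaries
#'
#' @param chromLengths named chromosome lengths (bp).
#' @param binSize bin size (bp).
#' @param nTads number of domains per chromosome.
#' @return named list of strictly increasing boundary bin indices.
#' @export
evenTadBoundaries <- function(chromLengths, binSize, nTads) {
    lapply(setNames(nm = names(chromLengths)), function(ch) {
        n <- ceiling(chromLengths[ch] / binSize)
        if (nTads < 2) return(integer())
        as.integer(round(seq_len(nTads - 1) * n / nTads))
    })
}

#' Alternating A/B checkerboard labels
#'
#' @param nBins number of bins.
#' @param period block width in bins.
#' @export
checkerboardLabels <- function(nBins, period) {
    c("A", "B")[((seq_len(nBins) - 1) %/% period) %% 2 + 1]
}

#' Specify a synthetic Hi-C cohort
#'
#' Builds a \linkS4class{SyntheticSpec}. The defaults describe the package's
#' reference toy system: one 10 Mb chromosome at 40 kb bins, power-law decay
#' with exponent 1, and eight equal TADs with a within-TAD boost of 2; no
#' compartments, loops, trans mass or group effect unless requested.
#'
#' @param chromLengths named numeric vector (bp).
#' @param binSize bin size (bp).
#' @param alpha decay exponent; cis probability at distance d bins is
#'   proportional to max(d, 1)^(-alpha).
#' @param compartments per-chromosome list of per-bin "A"/"B" labels, or NULL.
#' @param compStrength compartment strength c: same-label cells are scaled by
#'   (1 + c), opposite-label by (1 - c).
#' @param tadBoundaries per-chromosome list of interior boundary bins, or NULL
#'   for the default 8-domain layout; \code{list()} for none.
#' @param tadBoost within-TAD multiplicative boost t (>= 1).
#' @param loops data.frame (chrom, i, j) of loop pixels (bin indices, i < j).
#' @param loopBoost peak boost L at the loop center.
#' @param loopHalfWidth Gaussian footprint half-width in bins; the boost
#'   decays over a (2*halfWidth+1)^2 square.
#' @param transFrac fraction of total probability placed uniformly on trans
#'   cells (ignored, forced to 0, for single-chromosome genomes).
#' @param transBoost data.frame (chrom1, chrom2, factor) of per-block trans
#'   boosts emulating a rearrangement.
#' @param groupEffect list(chrom, startBin, endBin, factor): multiplicative
#'   factor applied to the affected group's expected map at cells whose bins
#'   both fall in the interval.
#' @return a validated \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(chromLengths = c(chrS = 1e7), binSize = 4e4,
                          alpha = 1,
                          compartments = list(), compStrength = 0.4,
                          tadBoundaries = NULL, tadBoost = 2,
                          loops = data.frame(chrom = character(),
                                             i = integer(), j = integer()),
                          loopBoost = 5, loopHalfWidth = 1L,
                          transFrac = if (length(chromLengths) > 1) 0.15 else 0,
                          transBoost = data.frame(chrom1 = character(),
                                                  chrom2 = character(),
                                                  factor = numeric()),
                          groupEffect = list()) {
    if (is.null(tadBoundaries))
        tadBoundaries <- evenTadBoundaries(chromLengths, binSize, 8)
    if (length(chromLengths) == 1) transFrac <- 0
    new("SyntheticSpec", chromLengths = chromLengths, binSize = binSize,
        alpha = alpha, compartments = compartments,
        compStrength = compStrength, tadBoundaries = tadBoundaries,
        tadBoost = tadBoost, loops = loops, loopBoost = loopBoost,
        loopHalfWidth = as.integer(loopHalfWidth), transFrac = transFrac,
        transBoost = transBoost, groupEffect = groupEffect)
}

#' Planted truth of a synthetic spec
#' @param spec a \linkS4class{SyntheticSpec}.
#' @export
plantedTruth <- function(spec) {
    new("PlantedTruth", labels = spec@compartments,
        boundaries = spec@tadBoundaries, loopPixels = spec@loops,
        groupEffect = spec@groupEffect)
}

#' Expected contact probability map of a synthetic spec
#'
#' Cis cells at distance d bins carry weight max(d, 1)^(-alpha), multiplied
#' by the TAD boost when both bins share a domain, by (1 +/- c) for same- or
#' opposite-compartment bins, by a Gaussian-decayed loop boost inside loop
#' footprints, and (optionally) by the group-effect factor. Trans cells share
#' a uniform fraction of the total mass. The result is normalized so the
#' upper triangle (with diagonal) sums to 1.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param applyGroupEffect apply \code{spec@groupEffect} (the affected group's
#'   map); default FALSE (the baseline group).
#' @return a \linkS4class{ProbabilityMap}.
#' @export
buildProbabilityMap <- function(spec, applyGroupEffect = FALSE) {
    bins <- genomeBins(spec@chromLengths, spec@binSize)
    ci <- chromBinIdx(bins)
    n <- nBins(bins)
    P <- matrix(0, n, n)
    for (ch in bins@chromNames) {
        idx <- ci[[ch]]
        nc <- length(idx)
        d <- abs(outer(seq_len(nc), seq_len(nc), "-"))
        blk <- pmax(d, 1)^(-spec@alpha)
        bd <- spec@tadBoundaries[[ch]]
        if (length(bd) && spec@tadBoost != 1) {
            tid <- findInterval(seq_len(nc), bd + 0.5) # domain id per bin
            same <- outer(tid, tid, "==")
            blk[same] <- blk[same] * spec@tadBoost
        }
        lab <- spec@compartments[[ch]]
        if (!is.null(lab) && spec@compStrength > 0) {
            if (length(lab) != nc)
                stop("compartment labels for ", ch, " must have one entry per bin")
            same <- outer(lab, lab, "==")
            blk <- blk * ifelse(same, 1 + spec@compStrength,
                                1 - spec@compStrength)
        }
        lp <- spec@loops[spec@loops$chrom == ch, , drop = FALSE]
        if (nrow(lp) && spec@loopBoost != 1) {
            hw <- spec@loopHalfWidth
            sig <- max(hw, 1) / 2
            off <- expand.grid(di = -hw:hw, dj = -hw:hw)
            g <- exp(-(off$di^2 + off$dj^2) / (2 * sig^2))
            for (r in seq_len(nrow(lp))) {
                a <- lp$i[r] + off$di; b <- lp$j[r] + off$dj
                ok <- a >= 1 & a <= nc & b >= 1 & b <= nc & a < b
                f <- 1 + (spec@loopBoost - 1) * g[ok]
                blk[cbind(a[ok], b[ok])] <- blk[cbind(a[ok], b[ok])] * f
                blk[cbind(b[ok], a[ok])] <- blk[cbind(b[ok], a[ok])] * f
            }
        }
        if (applyGroupEffect && length(spec@groupEffect) &&
            spec@groupEffect$chrom == ch) {
            ge <- spec@groupEffect
            sel <- ge$startBin:ge$endBin
            blk[sel, sel] <- blk[sel, sel] * ge$factor
        }
        P[idx, idx] <- blk
    }
    ut <- upper.tri(P, diag = TRUE)
    cisMass <- sum(P[ut])
    P <- P * ((1 - spec@transFrac) / cisMass)
    if (spec@transFrac > 0) {
        W <- matrix(0, n, n)
        cn <- bins@chromNames
        for (a in seq_along(cn)) for (b in seq_along(cn)) if (a != b)
            W[ci[[cn[a]]], ci[[cn[b]]]] <- 1
        if (nrow(spec@transBoost)) {
            for (r in seq_len(nrow(spec@transBoost))) {
                i1 <- ci[[spec@transBoost$chrom1[r]]]
                i2 <- ci[[spec@transBoost$chrom2[r]]]
                W[i1, i2] <- W[i1, i2] * spec@transBoost$factor[r]
                W[i2, i1] <- W[i2, i1] * spec@transBoost$factor[r]
            }
        }
        P <- P + W * (spec@transFrac / sum(W[ut]))
    }
    new("ProbabilityMap", prob = P, bins = bins, spec = spec)
}

#' Sample valid pairs from a probability map
#'
#' Draws N contacts multinomially over the upper-triangle cells, then places
#' each end uniformly within its bin with a uniform random strand.
#'
#' @param pmap a \linkS4class{ProbabilityMap}.
#' @param N number of pairs to draw.
#' @param seed integer RNG seed (explicit; global RNG state is untouched).
#' @return a \linkS4class{ValidPairSet}.
#' @export
sampleContacts <- function(pmap, N, seed) {
    stopifnot(N > 0)
    bins <- pmap@bins
    n <- nBins(bins)
    ut <- which(upper.tri(pmap@prob, diag = TRUE))
    p <- pmap@prob[ut]
    withSeed(seed, {
        cnt <- as.vector(rmultinom(1, N, p))
        nz <- cnt > 0
        cell <- rep(ut[nz], cnt[nz])
        i <- ((cell - 1) %% n) + 1L
        j <- ((cell - 1) %/% n) + 1L
        bt <- binTable(bins)
        w1 <- bt$end[i] - bt$start[i]
        w2 <- bt$end[j] - bt$start[j]
        rec <- data.frame(
            readID = sprintf("r%08d", seq_len(N)),
            chr1 = bt$chrom[i],
            pos1 = bt$start[i] + floor(runif(N) * w1) + 1,
            strand1 = c("+", "-")[1 + (runif(N) < 0.5)],
            chr2 = bt$chrom[j],
            pos2 = bt$start[j] + floor(runif(N) * w2) + 1,
            strand2 = c("+", "-")[1 + (runif(N) < 0.5)])
        validPairSet(rec, bins)
    })
}

#' Binomial thinning of a pair set
#'
#' Keeps each record independently with probability p — the standard device
#' for emulating technical replicates at reduced depth.
#'
#' @param pairs a \linkS4class{ValidPairSet}.
#' @param p retention probability in (0, 1].
#' @param seed integer RNG seed.
#' @export
thinReplicate <- function(pairs, p, seed) {
    stopifnot(p > 0, p <= 1)
    if (p == 1) return(pairs)
    withSeed(seed, {
        keep <- runif(nPairs(pairs)) < p
        validPairSet(pairs@records[keep, , drop = FALSE], pairs@genome)
    })
}

#' Generate a two-group synthetic cohort on disk
#'
#' Samples per-group valid-pairs files from the spec's expected map; the
#' second group's map carries the spec's group effect. Writes a chrom.sizes
#' file, one valid-pairs file per sample, a sample sheet, and the planted
#' truth as JSON.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param nPerGroup samples per group.
#' @param pairsPerSample valid pairs per sample.
#' @param dir output directory (created if needed).
#' @param seed base seed; sample s uses seed + s.
#' @param groupNames length-2 character, used in sample names.
#' @return list: \code{sheet} (data.frame sample, file, group), \code{truth}
#'   (\linkS4class{PlantedTruth}), \code{chromSizes}, \code{truthFile}.
#' @export
makeCohort <- function(spec, nPerGroup = 2, pairsPerSample = 2e6, dir,
                       seed = 1, groupNames = c("CTR", "CASE")) {
    stopifnot(nPerGroup >= 1, length(groupNames) == 2)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pm1 <- buildProbabilityMap(spec, applyGroupEffect = FALSE)
    pm2 <- if (length(spec@groupEffect))
        buildProbabilityMap(spec, applyGroupEffect = TRUE) else pm1
    csPath <- file.path(dir, "genome.chrom.sizes")
    writeChromSizes(pm1@bins, csPath)
    sheet <- NULL
    for (g in 1:2) for (s in seq_len(nPerGroup)) {
        name <- sprintf("%s-%d", groupNames[g], s)
        f <- file.path(dir, paste0(name, ".validPairs"))
        vp <- sampleContacts(if (g == 1) pm1 else pm2, pairsPerSample,
                             seed = seed + (g - 1) * nPerGroup + s)
        writeValidPairs(vp, f)
        sheet <- rbind(sheet, data.frame(sample = name, file = f,
                                         group = groupNames[g]))
    }
    truth <- plantedTruth(spec)
    truthFile <- file.path(dir, "planted_truth.json")
    jsonlite::write_json(
        list(labels = truth@labels, boundaries = truth@boundaries,
             loopPixels = truth@loopPixels, groupEffect = truth@groupEffect),
        truthFile, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(sheet = sheet, truth = truth, chromSizes = csPath,
         truthFile = truthFile)
}

#' @describeIn syntheticSpec display method
#' @param object a \linkS4class{SyntheticSpec}.
#' @export
setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d chrom(s), %s bp bins, alpha=%g, %d TAD boundary set(s), %d loop(s), trans %.2f\n",
        length(object@chromLengths), format(object@binSize, big.mark = ","),
        object@alpha, sum(lengths(object@tadBoundaries) > 0),
        nrow(object@loops), object@transFrac))
})
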
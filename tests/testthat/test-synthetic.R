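test_that("probability map follows a pure power law when no structure is planted", {
    spec <- syntheticSpec(chromLengths = c(c1 = 4e3), binSize = 1e3,
                          alpha = 1, tadBoundaries = list(), tadBoost = 1)
    pm <- buildProbabilityMap(spec)
    p <- pm@prob
    # off-diagonal decays as 1/d: ratios against the first superdiagonal
    expect_equal(p[1, 3] / p[1, 2], 1 / 2, tolerance = 1e-12)
    expect_equal(p[1, 4] / p[1, 2], 1 / 3, tolerance = 1e-12)
    # diagonal carried at d = 1 weight
    expect_equal(p[1, 1], p[1, 2], tolerance = 1e-12)
    expect_equal(sum(p[upper.tri(p, diag = TRUE)]), 1, tolerance = 1e-10)
    expect_equal(max(abs(p - t(p))), 0)
})

test_that("neutral factors leave the pure-decay map unchanged", {
    base <- buildProbabilityMap(decayOnlySpec(c(c1 = 2e6), 1e5))
    neutral <- buildProbabilityMap(syntheticSpec(
        chromLengths = c(c1 = 2e6), binSize = 1e5,
        compartments = list(c1 = checkerboardLabels(20, 5)), compStrength = 0,
        tadBoundaries = list(c1 = c(7L, 14L)), tadBoost = 1,
        loops = data.frame(chrom = "c1", i = 3L, j = 12L), loopBoost = 1))
    expect_equal(neutral@prob, base@prob, tolerance = 1e-12)
})

test_that("planted TADs boost within-domain cells by exactly t at matched distance", {
    t <- 2
    spec <- syntheticSpec(chromLengths = c(c1 = 2e6), binSize = 1e5,
                          tadBoundaries = list(c1 = 10L), tadBoost = t)
    p <- buildProbabilityMap(spec)@prob
    # brute force: per distance, mean within-TAD vs mean cross-boundary
    tid <- rep(1:2, each = 10)
    for (d in 2:6) {
        cells <- cbind(seq_len(20 - d), seq_len(20 - d) + d)
        within <- tid[cells[, 1]] == tid[cells[, 2]]
        expect_equal(mean(p[cells[within, , drop = FALSE]]) /
                     mean(p[cells[!within, , drop = FALSE]]), t,
                     tolerance = 1e-9)
    }
})

test_that("trans mass equals the stated fraction and planted trans boosts concentrate", {
    spec <- syntheticSpec(chromLengths = c(c1 = 2e6, c2 = 2e6, c3 = 2e6),
                          binSize = 1e5, tadBoundaries = list(), tadBoost = 1,
                          transFrac = 0.15,
                          transBoost = data.frame(chrom1 = "c1", chrom2 = "c3",
                                                  factor = 5))
    pm <- buildProbabilityMap(spec)
    p <- pm@prob
    ut <- upper.tri(p, diag = TRUE)
    cis <- matrix(FALSE, nrow(p), nrow(p))
    for (idx in HiCohort:::chromBinIdx(pm@bins)) cis[idx, idx] <- TRUE
    expect_equal(sum(p[ut & !cis]), 0.15, tolerance = 1e-10)
    b13 <- mean(p[1:20, 41:60]); b12 <- mean(p[1:20, 21:40])
    expect_equal(b13 / b12, 5, tolerance = 1e-9)
})

test_that("sampling conserves totals, honors the seed, and matches the multinomial law", {
    spec <- decayOnlySpec(c(c1 = 4e5), 1e5)  # 4 bins, 10 cells
    pm <- buildProbabilityMap(spec)
    v1 <- sampleContacts(pm, 1000, seed = 42)
    v2 <- sampleContacts(pm, 1000, seed = 42)
    expect_identical(pairRecords(v1), pairRecords(v2))
    expect_equal(nPairs(v1), 1000)
    # one-bin genome: every pair lands in the only cell
    one <- buildProbabilityMap(decayOnlySpec(c(c1 = 9e4), 1e5))
    vone <- sampleContacts(one, 1000, seed = 1)
    expect_true(all(pairRecords(vone)$chr1 == "c1" &
                    pairRecords(vone)$chr2 == "c1"))
    # chi-square GOF over 20 seeds: expected vs realized cell counts
    ut <- which(upper.tri(pm@prob, diag = TRUE))
    expProb <- pm@prob[ut]
    n <- 4L
    rejections <- 0L
    for (s in 1:20) {
        vp <- sampleContacts(pm, 5000, seed = 1000 + s)
        r <- pairRecords(vp)
        i <- (r$pos1 - 1) %/% 1e5 + 1
        j <- (r$pos2 - 1) %/% 1e5 + 1
        cell <- pmin(i, j) + (pmax(i, j) - 1) * n
        obs <- as.numeric(table(factor(cell, levels = ut)))
        pval <- suppressWarnings(stats::chisq.test(obs, p = expProb)$p.value)
        if (pval < 0.01) rejections <- rejections + 1L
    }
    expect_lte(rejections, 1L)
})

test_that("thinning is a per-record Bernoulli with the stated retention", {
    spec <- decayOnlySpec(c(c1 = 1e6), 1e5)
    vp <- sampleContacts(buildProbabilityMap(spec), 1e5, seed = 3)
    expect_identical(thinReplicate(vp, 1, seed = 1), vp)
    t1 <- thinReplicate(vp, 0.5, seed = 10)
    t2 <- thinReplicate(vp, 0.5, seed = 11)
    # kept count within 4 sd of N/2
    expect_lt(abs(nPairs(t1) - 5e4), 4 * sqrt(1e5 * 0.25))
    expect_false(identical(pairRecords(t1), pairRecords(t2)))
    # both are subsets of the parent
    expect_true(all(pairRecords(t1)$readID %in% pairRecords(vp)$readID))
})

test_that("cohorts carry the planted truth and group effect in expectation", {
    ge <- list(chrom = "c1", startBin = 5, endBin = 5, factor = 3)
    spec <- syntheticSpec(chromLengths = c(c1 = 2e6), binSize = 1e5,
                          tadBoundaries = list(c1 = 10L), tadBoost = 1.5,
                          groupEffect = ge)
    td <- withr::local_tempdir()
    co <- makeCohort(spec, nPerGroup = 2, pairsPerSample = 2e5, dir = td,
                     seed = 5)
    expect_identical(co$truth@boundaries, spec@tadBoundaries)
    expect_true(file.exists(co$chromSizes))
    expect_true(all(file.exists(co$sheet$file)))
    expect_equal(nrow(co$sheet), 4)
    gb <- readChromSizes(co$chromSizes, 1e5)
    counts <- vapply(co$sheet$file, function(f) {
        m <- binContacts(readValidPairs(f, gb), c(c1 = 2e6), 1e5)
        m@mat[5, 5]
    }, numeric(1))
    g1 <- sum(counts[co$sheet$group == "CTR"])
    g2 <- sum(counts[co$sheet$group == "CASE"])
    # pooled group-2 count at the boosted pixel ~ 3x group-1 at matched depth
    expect_gt(g2 / g1, 2)
    expect_lt(g2 / g1, 4.5)
    # a factor-1 effect leaves the two groups' expected maps identical
    spec1 <- syntheticSpec(chromLengths = c(c1 = 2e6), binSize = 1e5,
                           groupEffect = list(chrom = "c1", startBin = 5,
                                              endBin = 5, factor = 1))
    expect_equal(buildProbabilityMap(spec1, applyGroupEffect = TRUE)@prob,
                 buildProbabilityMap(spec1, applyGroupEffect = FALSE)@prob)
})

test_that("invalid spec inputs are rejected with a message", {
    expect_error(syntheticSpec(chromLengths = c(c1 = 1e6), binSize = 1e5,
                               tadBoundaries = list(c1 = c(5L, 5L))),
                 "strictly increasing")
    expect_error(syntheticSpec(chromLengths = c(c1 = 1e6), binSize = 1e5,
                               loops = data.frame(chrom = "c1", i = 2L,
                                                  j = 100L)),
                 "out of range")
    expect_error(sampleContacts(
        buildProbabilityMap(decayOnlySpec(c(c1 = 1e6), 1e5)), N = 0,
        seed = 1))
})
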
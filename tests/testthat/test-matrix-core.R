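gb2 <- genomeBins(c(c1 = 1e6, c2 = 5e5), binSize = 1e5)

test_that("valid-pairs parsing honors the 7+ column dialect and skip rules", {
    f <- writeToyPairsFile(c(
        "r1\tc1\t100\t+\tc1\t50100\t-\textra\tcols",
        "r2\tc1\t999999\t-\tc2\t1\t+",
        "r3\tchrBad\t100\t+\tc1\t200\t-",
        "r4\tc1\t2000000\t+\tc1\t100\t-"))   # pos1 beyond c1
    expect_warning(vp <- readValidPairs(f, gb2), "2 invalid")
    expect_equal(nPairs(vp), 2)
    expect_equal(vp@nSkipped, 2L)
    expect_equal(pairRecords(vp)$chr2, c("c1", "c2"))
    expect_error(readValidPairs(f, gb2, strict = TRUE), "strict")
    # empty file
    f0 <- writeToyPairsFile(character())
    expect_warning(v0 <- readValidPairs(f0, gb2), "empty")
    expect_equal(nPairs(v0), 0)
    # round trip
    out <- tempfile()
    writeValidPairs(vp, out)
    expect_equal(pairRecords(readValidPairs(out, gb2)), pairRecords(vp))
})

test_that("binning fills both triangles and conserves record counts", {
    rec <- data.frame(readID = c("a", "b", "c", "d"),
                      chr1 = c("c1", "c1", "c1", "c1"),
                      pos1 = c(100, 250001, 250001, 250001),
                      strand1 = "+",
                      chr2 = c("c1", "c1", "c1", "c1"),
                      pos2 = c(100, 750001, 750001, 750001),
                      strand2 = "-")
    vp <- validPairSet(rec, gb2)
    cm <- binContacts(vp, c(c1 = 1e6, c2 = 5e5), 1e5)
    m <- contactMap(cm)
    expect_equal(m[1, 1], 1)           # diagonal self-contact counted once
    expect_equal(m[3, 8], 3)           # 3 pairs between bins 3 and 8
    expect_equal(m[8, 3], 3)           # symmetrized
    expect_equal(sum(m[upper.tri(m, diag = TRUE)]), 4)
    # conservation on random input
    spec <- decayOnlySpec(c(c1 = 1e6), 1e5)
    vpr <- sampleContacts(buildProbabilityMap(spec), 1e4, seed = 9)
    mr <- contactMap(binContacts(vpr, c(c1 = 1e6), 1e5))
    expect_equal(sum(mr[upper.tri(mr, diag = TRUE)]), 1e4)
    # idempotent through serialization
    f <- tempfile(); fb <- tempfile()
    cmr <- binContacts(vpr, c(c1 = 1e6), 1e5)
    writeTripletMatrix(cmr, f, fb)
    back <- readTripletMatrix(f, fb)
    expect_equal(contactMap(back), contactMap(cmr))
})

test_that("ICE is a fixed point on balanced input and uses the standard defaults", {
    n <- 10
    m <- matrix(1, n, n)
    cm <- new("ContactMatrix", bins = genomeBins(c(c1 = n * 1e5), 1e5),
              mat = m, bias = rep(1, n), mask = rep(FALSE, n),
              state = "raw", totalPairs = sum(m))
    ic <- iceNormalize(cm, lowPct = 0)
    expect_equal(contactMap(ic), m)
    expect_equal(biasVector(ic), rep(1, n))
    expect_identical(formals(iceNormalize)$maxIter, 100)
    expect_identical(formals(iceNormalize)$lowPct, 0.02)
    expect_identical(formals(iceNormalize)$highPct, 0)
    expect_identical(formals(iceNormalize)$eps, 0.1)
    expect_error(iceNormalize(new("ContactMatrix",
        bins = genomeBins(c(c1 = 3e5), 1e5), mat = matrix(0, 3, 3),
        bias = rep(1, 3), mask = rep(FALSE, 3), state = "raw",
        totalPairs = 0)), "nothing to balance")
})

test_that("ICE recovers a constructed-bias matrix proportional to the truth", {
    # T doubly balanced 5x5 (symmetric, equal row sums)
    T0 <- matrix(c(4, 2, 2, 1, 1,
                   2, 3, 1, 2, 2,
                   2, 1, 3, 2, 2,
                   1, 2, 2, 4, 1,
                   1, 2, 2, 1, 4), 5, 5, byrow = TRUE)
    expect_true(all(rowSums(T0) == 10))
    b <- c(1, 2, 1, 0.5, 1)
    O <- diag(b) %*% T0 %*% diag(b)
    cm <- new("ContactMatrix", bins = genomeBins(c(c1 = 5e5), 1e5),
              mat = O, bias = rep(1, 5), mask = rep(FALSE, 5),
              state = "raw", totalPairs = sum(O))
    ic <- iceNormalize(cm, maxIter = 10000, lowPct = 0, eps = 1e-8)
    got <- contactMap(ic) / mean(contactMap(ic))
    expect_equal(got, T0 / mean(T0), tolerance = 1e-6)
    # raw is recoverable through the bias vector
    bb <- biasVector(ic)
    expect_equal(contactMap(ic) * outer(bb, bb), O, tolerance = 1e-6)
})

test_that("ICE row-sum dispersion decreases monotonically across iterations", {
    spec <- decayOnlySpec(c(c1 = 5e6), 1e5)  # 50 bins
    raw <- binContacts(sampleContacts(buildProbabilityMap(spec), 1e5,
                                      seed = 11), c(c1 = 5e6), 1e5)
    cvs <- vapply(1:6, function(k) {
        ic <- iceNormalize(raw, maxIter = k, lowPct = 0, eps = 0)
        rs <- rowSums(contactMap(ic))
        sd(rs) / mean(rs)
    }, numeric(1))
    expect_true(all(diff(cvs) <= 1e-10))
})

test_that("resolution decision matches enumeration and flags the achieved sizes", {
    # depths [2000 x 9, 500 x 1]: the 80th-percentile position (8) holds 2000
    expect_equal(HiCohort:::percentileDepth(c(rep(2000, 9), 500), 0.8), 2000)
    # boundary case: all depths exactly at the threshold still achieve
    expect_equal(HiCohort:::percentileDepth(rep(1000, 10), 0.8), 1000)
    # defaults follow the standard grid and threshold
    expect_identical(eval(formals(mapResolution)$depthThreshold), 1000)
    expect_identical(eval(formals(mapResolution)$percentile), 0.80)
    expect_identical(sort(eval(formals(mapResolution)$candidateSizes)),
                     sort(c(1e6, 5e5, 2e5, 1e5, 4e4, 2e4, 1e4, 5e3, 1e3)))
})

test_that("percentile-depth statistic equals a brute-force oracle on random vectors", {
    set.seed(77)
    for (k in 1:1000) {
        n <- sample(5:200, 1)
        depth <- rpois(n, lambda = sample(1:2000, 1))
        p <- runif(1, 0.05, 0.95)
        s <- sort(depth, decreasing = TRUE)
        oracle <- s[max(1, ceiling(p * n))]
        expect_identical(HiCohort:::percentileDepth(depth, p), oracle)
    }
})

test_that("map resolution counts pair ends and reports the finest achieved size", {
    spec <- decayOnlySpec(c(c1 = 1e6), 1e5)
    vp <- sampleContacts(buildProbabilityMap(spec), 6000, seed = 13)
    rr <- mapResolution(vp, c(c1 = 1e6),
                        candidateSizes = c(1e5, 1e4), depthThreshold = 1000)
    # 12000 ends over 10 bins of 100 kb: ~1200 each, achieved at 100 kb only
    expect_true(rr$table$achieved[rr$table$binSize == 1e5])
    expect_false(rr$table$achieved[rr$table$binSize == 1e4])
    expect_equal(rr$finestAchieved, 1e5)
    ends <- c((pairRecords(vp)$pos1 - 1) %/% 1e5,
              (pairRecords(vp)$pos2 - 1) %/% 1e5) + 1
    expect_equal(sort(rr$table$nBins), c(10, 100))
    expect_equal(rr$table$decisionDepth[rr$table$binSize == 1e5],
                 HiCohort:::percentileDepth(tabulate(ends, 10), 0.8))
})

test_that("cis means dominate trans means and planted trans boosts are flagged", {
    spec <- syntheticSpec(chromLengths = c(c1 = 2e6, c2 = 2e6, c3 = 2e6,
                                           c4 = 2e6),
                          binSize = 1e5, tadBoundaries = list(), tadBoost = 1,
                          transFrac = 0.15,
                          transBoost = data.frame(chrom1 = "c1",
                                                  chrom2 = "c3", factor = 8))
    vp <- sampleContacts(buildProbabilityMap(spec), 4e5, seed = 21)
    cm <- binContacts(vp, spec@chromLengths, 1e5)
    ct <- cisTransSummary(cm)
    expect_true(min(ct$cis$mean) > max(ct$trans$mean[!ct$trans$flagged]))
    flagged <- ct$trans[ct$trans$flagged, ]
    expect_equal(nrow(flagged), 1)
    expect_equal(c(flagged$chrom1, flagged$chrom2), c("c1", "c3"))
    # uniform matrix: no flags
    n <- 20
    u <- new("ContactMatrix", bins = genomeBins(c(a = 1e6, b = 1e6), 1e5),
             mat = matrix(1, n, n), bias = rep(1, n), mask = rep(FALSE, n),
             state = "raw", totalPairs = n^2)
    expect_false(any(cisTransSummary(u)$trans$flagged))
})

test_that("delta matrices vanish under equality and depth rescaling", {
    spec <- decayOnlySpec(c(c1 = 2e6), 1e5)
    a <- sampledIced(spec, N = 1e5, seed = 31)
    expect_equal(max(abs(deltaMatrix(a, a)), na.rm = TRUE), 0)
    doubled <- new("ContactMatrix", bins = a@bins, mat = a@mat * 2,
                   bias = a@bias, mask = a@mask, state = a@state,
                   totalPairs = a@totalPairs)
    expect_equal(max(abs(deltaMatrix(a, doubled)), na.rm = TRUE), 0,
                 tolerance = 1e-10)
    b <- sampledIced(decayOnlySpec(c(c1 = 3e6), 1e5), N = 1e5, seed = 32)
    expect_error(deltaMatrix(a, b), "binning")
})

test_that("planted group effects surface as the largest delta cells", {
    ge <- list(chrom = "c1", startBin = 8, endBin = 12, factor = 4)
    spec <- syntheticSpec(chromLengths = c(c1 = 5e6), binSize = 1e5,
                          tadBoundaries = list(), tadBoost = 1,
                          groupEffect = ge)
    m1 <- binContacts(
        sampleContacts(buildProbabilityMap(spec, FALSE), 1e6, seed = 41),
        spec@chromLengths, 1e5)
    m2 <- binContacts(
        sampleContacts(buildProbabilityMap(spec, TRUE), 1e6, seed = 42),
        spec@chromLengths, 1e5)
    d <- deltaMatrix(m2, m1)
    top10 <- arrayInd(order(-abs(d))[1:10], dim(d))
    expect_true(all(top10 >= 8 & top10 <= 12))
    expect_gt(min(d[top10]), 0)
})
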
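plantedLoops <- data.frame(
    chrom = "chrS",
    i = c(20L, 60L, 100L, 140L, 180L, 40L, 120L, 200L),
    j = c(50L, 95L, 130L, 170L, 215L, 80L, 160L, 240L))

loopSpec <- function(L = 5) syntheticSpec(loops = plantedLoops, loopBoost = L,
                                          loopHalfWidth = 1,
                                          tadBoundaries = list(), tadBoost = 1)

test_that("loop calling demands a balanced matrix and honors threshold limits", {
    raw <- binContacts(sampleContacts(buildProbabilityMap(loopSpec()), 1e5,
                                      seed = 101), toyLengths, 4e4)
    expect_error(callLoops(raw), "balanced")
    ic <- iceNormalize(raw)
    empty <- callLoops(ic, foldMin = Inf)
    expect_equal(nrow(loopPixels(empty)), 0)
    expect_gt(empty@nTested, 0)
})

test_that("planted loops are recovered and nulls stay clean", {
    ic <- sampledIced(loopSpec(), N = 2e6, seed = 102)
    ls <- callLoops(ic)
    called <- loopPixels(ls)
    hit <- vapply(seq_len(nrow(plantedLoops)), function(k)
        any(abs(called$i - plantedLoops$i[k]) <= 1 &
            abs(called$j - plantedLoops$j[k]) <= 1), logical(1))
    expect_gte(mean(hit), 0.8)
    # null maps over several seeds: calls bounded by the FDR budget
    nullCalls <- vapply(1:5, function(s) {
        icN <- sampledIced(decayOnlySpec(), N = 5e5, seed = 110 + s)
        lsN <- callLoops(icN)
        nrow(lsN@pixels) / max(1, lsN@nTested)
    }, numeric(1))
    expect_lte(mean(nullCalls), 0.05 * 0.1)
    # loop pixels respect the distance band and ordering invariants
    expect_true(all(called$j > called$i))
    expect_true(all(called$distance >= 2 * 4e4 & called$distance <= 2e6))
})

test_that("loop calling is invariant to the balancing scale convention", {
    # rescaling the balanced matrix with the biases absorbing the factor
    # (same underlying raw counts) must not change the calls
    ic <- sampledIced(loopSpec(), N = 1e6, seed = 103)
    ic2 <- new("ContactMatrix", bins = ic@bins, mat = ic@mat * 3,
               bias = ic@bias / sqrt(3), mask = ic@mask, state = "iced",
               totalPairs = ic@totalPairs)
    l1 <- loopPixels(callLoops(ic))
    l2 <- loopPixels(callLoops(ic2))
    expect_equal(l1[, c("chrom", "i", "j")], l2[, c("chrom", "i", "j")])
})

test_that("APA scores reflect planted boosts, stay at 1 on nulls, and average submatrices", {
    ic <- sampledIced(loopSpec(), N = 2e6, seed = 104)
    oe <- observedOverExpected(ic)
    ap <- apa(oe, plantedLoops, W = 5, corner = 3)
    expect_equal(apaScore(ap), 5, tolerance = 0.2 * 5)
    expect_equal(dim(ap@agg), c(11, 11))
    # uniform O/E: score exactly 1
    n <- 60
    u <- new("ContactMatrix", bins = genomeBins(c(c1 = n * 1e5), 1e5),
             mat = matrix(1, n, n), bias = rep(1, n), mask = rep(FALSE, n),
             state = "oe", totalPairs = n^2)
    expect_equal(apaScore(apa(u, data.frame(chrom = "c1", i = 10L, j = 40L))),
                 1)
    # a single anchor reproduces that submatrix exactly
    a1 <- data.frame(chrom = "chrS", i = 60L, j = 95L)
    apOne <- apa(oe, a1, W = 3, corner = 2)
    expect_equal(apOne@agg, contactMap(oe)[57:63, 92:98], tolerance = 1e-12)
    # null anchors concentrate at score 1 in the mean over seeds
    scores <- vapply(1:20, function(s) {
        icN <- sampledIced(decayOnlySpec(), N = 1e6, seed = 200 + s)
        apaScore(apa(observedOverExpected(icN), plantedLoops))
    }, numeric(1))
    expect_equal(mean(scores), 1, tolerance = 0.1)
    # anchors too close to the diagonal or edges are skipped and counted
    bad <- data.frame(chrom = "chrS", i = c(2L, 100L), j = c(8L, 104L))
    expect_error(apa(oe, bad), "no usable anchors")
})

test_that("APA differencing against a reference is exact and antisymmetric", {
    ic1 <- sampledIced(loopSpec(), N = 1e6, seed = 106)
    ic2 <- sampledIced(decayOnlySpec(), N = 1e6, seed = 107)
    a1 <- apa(observedOverExpected(ic1), plantedLoops)
    a2 <- apa(observedOverExpected(ic2), plantedLoops)
    self <- apaVsReference(a1, a1)
    expect_equal(max(abs(self@diff)), 0)
    expect_equal(self@scoreDiff, 0)
    d12 <- apaVsReference(a1, a2)
    d21 <- apaVsReference(a2, a1)
    expect_equal(d12@diff, -d21@diff)
    # sample with planted loops is enriched at the center over the null ref
    expect_gt(d12@diff[6, 6], 0)
    expect_gt(d12@scoreDiff, 0)
})

test_that("loops serialize to BEDPE and longrange (valid even when empty)", {
    ic <- sampledIced(loopSpec(), N = 1e6, seed = 108)
    ls <- callLoops(ic)
    f <- tempfile(fileext = ".bedpe")
    writeLoopsBedpe(ls, ic@bins, f)
    lines <- readLines(f)
    expect_match(lines[1], "^#chrom1")
    expect_equal(length(lines) - 1, nrow(loopPixels(ls)))
    fields <- strsplit(lines[-1], "\t")
    expect_true(all(lengths(fields) == 8))
    # empty set still writes a parseable header-only file
    emptySet <- callLoops(ic, foldMin = Inf)
    f2 <- tempfile(fileext = ".bedpe")
    writeLoopsBedpe(emptySet, ic@bins, f2)
    expect_equal(readLines(f2), lines[1])
})
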
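smallCohortMats <- function(groupFactor = NULL, nPerGroup = 2, N = 2e5,
                            seed = 1) {
    ge <- if (is.null(groupFactor)) list() else
        list(chrom = "chrS", startBin = 20, endBin = 24,
             factor = groupFactor)
    spec <- syntheticSpec(chromLengths = c(chrS = 5e6), binSize = 1e5,
                          tadBoundaries = list(), tadBoost = 1,
                          groupEffect = ge)
    pm1 <- buildProbabilityMap(spec, applyGroupEffect = FALSE)
    pm2 <- buildProbabilityMap(spec, applyGroupEffect = length(ge) > 0)
    mats <- c(
        lapply(seq_len(nPerGroup), function(s) binContacts(
            sampleContacts(pm1, N, seed = seed + s), spec@chromLengths, 1e5)),
        lapply(seq_len(nPerGroup), function(s) binContacts(
            sampleContacts(pm2, N, seed = seed + nPerGroup + s),
            spec@chromLengths, 1e5)))
    list(mats = mats, groups = rep(c("CTR", "CASE"), each = nPerGroup))
}

test_that("joint normalization is near-identity on identical matrices", {
    ic <- sampledIced(decayOnlySpec(c(c1 = 4e6), 1e5), N = 1e5, seed = 141)
    out <- jointNormalize(list(ic, ic, ic))
    for (o in out) {
        expect_identical(matrixState(o), "fastlo")
        expect_equal(contactMap(o), contactMap(ic), tolerance = 0.02)
    }
    expect_error(jointNormalize(list(ic)), "at least 2")
})

test_that("joint normalization removes a constructed distance-dependent bias", {
    base <- sampledIced(decayOnlySpec(c(c1 = 1e7), 1e5), N = 1e6, seed = 142)
    n <- nBins(base@bins)
    d <- abs(outer(seq_len(n), seq_len(n), "-")) * 1e5
    g <- 1.4 * ((d + 1e5) / 1e5)^0.15        # smooth monotone distance bias
    biased <- new("ContactMatrix", bins = base@bins, mat = base@mat * g,
                  bias = base@bias, mask = base@mask, state = "iced",
                  totalPairs = base@totalPairs)
    out <- jointNormalize(list(base, biased))
    px <- HiCohort:::pixelFrame(out)
    M <- log2(px$IF2 + 0.5) - log2(px$IF1 + 0.5)
    strat <- split(M, ceiling(pmax(px$distance, 1e5) / 1e6))
    resid <- vapply(strat, mean, numeric(1))
    expect_lt(max(abs(resid)), 0.05)
})

test_that("the exact test returns p = 1 when the two groups are the same data", {
    ic1 <- sampledIced(decayOnlySpec(c(c1 = 3e6), 1e5), N = 5e4, seed = 143)
    ic2 <- sampledIced(decayOnlySpec(c(c1 = 3e6), 1e5), N = 5e4, seed = 144)
    norm <- jointNormalize(list(ic1, ic2, ic1, ic2))
    dt <- exactTestDiff(norm, c("g1", "g1", "g2", "g2"))
    expect_true(all(dt$p == 1))
    expect_error(exactTestDiff(norm, c("a", "a", "a", "a")), "two groups")
})

test_that("the binomial reduction agrees with an independent exact implementation", {
    skip_if_not_installed("edgeR")
    cases <- expand.grid(y1 = c(0, 3, 10, 25), Tt = c(10, 25, 60))
    cases <- cases[cases$y1 <= cases$Tt, ]
    for (k in seq_len(nrow(cases))) {
        y1 <- cases$y1[k]; Tt <- cases$Tt[k]
        mine <- HiCohort:::exactTestPixel(y1, Tt, n1 = 2, n2 = 2, phi = 0)
        ref <- edgeR::binomTest(y1, Tt - y1, p = 0.5)
        expect_equal(mine, ref, tolerance = 1e-8,
                     label = sprintf("y1=%d T=%d", y1, Tt))
    }
})

test_that("null cohorts are calibrated: the q < 0.05 fraction stays below 0.05", {
    worst <- vapply(1:20, function(s) {
        co <- smallCohortMats(groupFactor = NULL, N = 1e5, seed = 150 + 7 * s)
        dt <- exactTestDiff(jointNormalize(co$mats), co$groups)
        mean(dt$q < 0.05, na.rm = TRUE)
    }, numeric(1))
    expect_lte(max(worst), 0.05)
    # empirical p-value distribution is not anti-conservative
    co <- smallCohortMats(groupFactor = NULL, N = 1e5, seed = 999)
    dt <- exactTestDiff(jointNormalize(co$mats), co$groups)
    for (a in c(0.01, 0.05, 0.1, 0.25))
        expect_lte(mean(dt$p <= a), a + 0.02)
})

test_that("a planted 3x locus is detected with correct sign and location", {
    co <- smallCohortMats(groupFactor = 3, N = 5e5, seed = 170)
    dt <- exactTestDiff(jointNormalize(co$mats), co$groups)
    eff <- dt$i >= 20 & dt$i <= 24 & dt$j >= 20 & dt$j <= 24
    expect_equal(sum(eff), 15)
    expect_gte(mean(dt$q[eff] < 0.05), 0.8)
    # CASE is the boosted group: M = log2(CASE/CTR) > 0 at the locus
    expect_gt(mean(dt$M[eff], na.rm = TRUE), 1)
    # top-|M| pixels concentrate in the locus
    top <- order(-abs(dt$M))[1:15]
    expect_gte(mean(eff[top]), 0.6)
})

test_that("the DiffTable export carries MD-composite columns", {
    co <- smallCohortMats(groupFactor = 3, N = 1e5, seed = 180)
    norm <- jointNormalize(co$mats)
    dt <- exactTestDiff(norm, co$groups)
    f <- tempfile(fileext = ".tsv")
    writeDiffTable(dt, norm[[1]]@bins, f)
    back <- read.delim(f)
    expect_named(back, c("chrom", "start1", "start2", "D", "M", "p", "q",
                         "significant"))
    expect_equal(nrow(back), nrow(dt))
    expect_true(all(back$q >= back$p - 1e-12, na.rm = TRUE))
})
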
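# Shared fixtures, all generated in code.

# the reference toy system: one 10 Mb chromosome, 40 kb bins (250 bins)
toyLengths <- c(chrS = 1e7)

# decay-only spec (no TADs/compartments/loops)
decayOnlySpec <- function(chromLengths = toyLengths, binSize = 4e4,
                          alpha = 1) {
    syntheticSpec(chromLengths = chromLengths, binSize = binSize,
                  alpha = alpha, tadBoundaries = list(), tadBoost = 1)
}

# a balanced toy matrix sampled from a spec
sampledIced <- function(spec, N = 2e6, seed = 1) {
    pm <- buildProbabilityMap(spec)
    vp <- sampleContacts(pm, N, seed = seed)
    iceNormalize(binContacts(vp, spec@chromLengths, spec@binSize))
}

# small deterministic valid-pairs file
writeToyPairsFile <- function(lines, path = tempfile(fileext = ".validPairs")) {
    writeLines(lines, path)
    path
}
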
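Package: HiCohort
Title: Comparative Hi-C Analysis for Small Cohorts with Planted-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end comparative analysis of Hi-C contact data for small
    cohorts of samples: parsing of valid-pairs text, binning into genome-wide
    contact matrices, iterative correction (ICE) balancing, percentile-depth
    map-resolution determination, distance-decay and relative contact
    probability curves with LOWESS expected models, A/B compartment calling by
    eigenvector decomposition of the observed/expected correlation matrix with
    group-wise switch detection, insulation-score TAD calling, local-neighborhood
    (donut) loop detection with aggregate peak analysis, stratum-adjusted
    correlation coefficients for reproducibility, and joint loess normalization
    with exact-test differential interaction detection. A synthetic contact-map
    generator plants known distance decay, compartments, TADs, loops, replicate
    thinning and group-specific effects so that every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
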
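#' @import methods
#' @importFrom stats cor dbinom dnbinom lowess median p.adjust ppois quantile
#'   rbinom rmultinom runif sd approx setNames
#' @importFrom utils head tail
NULL

#' Genome binning scheme
#'
#' Partition of a genome into fixed-size bins. Bins are 0-based half-open
#' intervals \code{[k*B, (k+1)*B)}; the last bin of each chromosome may be
#' short. Global bin indices run over chromosomes in the order given.
#'
#' @slot chromNames character, chromosome names.
#' @slot chromLengths numeric, chromosome lengths in bp (same order).
#' @slot binSize numeric, bin width B in bp.
#' @slot nBinsPerChrom integer, \code{ceiling(length/B)} per chromosome.
#' @slot offsets integer, 0-based global offset of each chromosome's first bin.
#' @export
setClass("GenomeBins",
    representation(
        chromNames = "character",
        chromLengths = "numeric",
        binSize = "numeric",
        nBinsPerChrom = "integer",
        offsets = "integer"
    )
)

setValidity("GenomeBins", function(object) {
    msg <- NULL
    if (length(object@chromNames) != length(object@chromLengths))
        msg <- c(msg, "chromNames and chromLengths differ in length")
    if (anyDuplicated(object@chromNames))
        msg <- c(msg, "duplicated chromosome names")
    if (length(object@binSize) != 1L || object@binSize <= 0)
        msg <- c(msg, "binSize must be a single positive number")
    if (any(object@chromLengths <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    exp_n <- as.integer(ceiling(object@chromLengths / object@binSize))
    if (!identical(exp_n, object@nBinsPerChrom))
        msg <- c(msg, "nBinsPerChrom inconsistent with lengths and binSize")
    if (!identical(object@offsets,
                   as.integer(cumsum(c(0L, head(object@nBinsPerChrom, -1L))))))
        msg <- c(msg, "offsets inconsistent with nBinsPerChrom")
    if (is.null(msg)) TRUE else msg
})

#' Set of Hi-C valid contact pairs
#'
#' Parsed valid-pairs records: for each ligation contact, chromosome,
#' 1-based position and strand of both ends, plus a read identifier.
#'
#' @slot records data.frame with columns readID, chr1, pos1, strand1,
#'   chr2, pos2, strand2.
#' @slot genome \linkS4class{GenomeBins} (binSize irrelevant here; carries the
#'   chromosome universe used for validation).
#' @slot nSkipped integer, malformed/off-genome input lines dropped at parse.
#' @export
setClass("ValidPairSet",
    representation(
        records = "data.frame",
        genome = "GenomeBins",
        nSkipped = "integer"
    )
)

setValidity("ValidPairSet", function(object) {
    req <- c("readID", "chr1", "pos1", "strand1", "chr2", "pos2", "strand2")
    if (!all(req %in% names(object@records)))
        return(paste("records must contain columns:", paste(req, collapse = ", ")))
    r <- object@records
    if (nrow(r)) {
        if (!all(r$chr1 %in% object@genome@chromNames) ||
            !all(r$chr2 %in% object@genome@chromNames))
            return("records reference chromosomes absent from the genome")
        len <- setNames(object@genome@chromLengths, object@genome@chromNames)
        if (any(r$pos1 < 1) || any(r$pos2 < 1) ||
            any(r$pos1 > len[r$chr1]) || any(r$pos2 > len[r$chr2]))
            return("positions outside chromosome bounds")
    }
    TRUE
})

#' Binned Hi-C contact matrix
#'
#' Genome-wide symmetric contact matrix at a fixed bin size, with the ICE
#' bias vector, a low-coverage bin mask, and a normalization state flag.
#' Cis blocks are the diagonal chromosome blocks; everything else is trans.
#'
#' @slot bins \linkS4class{GenomeBins}.
#' @slot mat numeric matrix, genome-wide and symmetric; counts when
#'   \code{state == "raw"}, balanced values after ICE, ratios after O/E.
#' @slot bias numeric, per-bin ICE bias b_i (1 when unbalanced, NA on masked
#'   bins after balancing).
#' @slot mask logical, TRUE for bins filtered out (low coverage).
#' @slot state character, one of "raw", "iced", "oe", "fastlo".
#' @slot totalPairs numeric, number of records binned into the matrix.
#' @export
setClass("ContactMatrix",
    representation(
        bins = "GenomeBins",
        mat = "matrix",
        bias = "numeric",
        mask = "logical",
        state = "character",
        totalPairs = "numeric"
    )
)

setValidity("ContactMatrix", function(object) {
    n <- sum(object@bins@nBinsPerChrom)
    msg <- NULL
    if (!all(dim(object@mat) == c(n, n)))
        msg <- c(msg, "matrix dimensions do not match the binning scheme")
    if (length(object@bias) != n || length(object@mask) != n)
        msg <- c(msg, "bias/mask length must equal the number of bins")
    if (!object@state %in% c("raw", "iced", "oe", "fastlo"))
        msg <- c(msg, "unknown normalization state")
    m <- object@mat
    if (n > 0 && n <= 2000L) {  # full symmetry check only at small scale
        d <- abs(m - t(m))
        if (max(d[!is.na(d)], 0) > 1e-6 * (1 + max(abs(m), na.rm = TRUE)))
            msg <- c(msg, "matrix is not symmetric")
    }
    if (any(m[!is.na(m)] < 0))
        msg <- c(msg, "negative contact values")
    if (is.null(msg)) TRUE else msg
})

#' Distance-decay / relative contact probability curve
#'
#' Distance-stratified observed mean contact values, optional LOWESS expected
#' values, and per-chromosome RCP (observed normalized to unit sum over
#' strata at positive distance). Genome-wide rows use chrom ".genome".
#'
#' @slot table data.frame: chrom, distance (bp, stratum upper edge; 0 for the
#'   diagonal stratum), observed, expected, rcp, n (cell count).
#' @slot stratumBp numeric stratum width in bp.
#' @slot binSize numeric bin size of the source matrix.
#' @slot f numeric LOWESS fraction (NA until the expected part is fitted).
#' @export
setClass("DecayCurve",
    representation(
        table = "data.frame",
        stratumBp = "numeric",
        binSize = "numeric",
        f = "numeric"
    )
)

#' A/B compartment track
#'
#' Per-bin leading eigenvector (E1) of the Pearson correlation matrix of the
#' observed/expected contact map, with A/B labels by sign after orientation
#' against a covariate (typically gene density).
#'
#' @slot bins \linkS4class{GenomeBins}.
#' @slot e1 numeric per-bin eigenvector value (NA on masked bins).
#' @slot label character per-bin "A", "B" or NA.
#' @slot evShare numeric named per-chromosome explained-variance share of E1.
#' @slot oriented logical, TRUE after orientation.
#' @slot covariateName character, name of the orientation covariate.
#' @export
setClass("CompartmentTrack",
    representation(
        bins = "GenomeBins",
        e1 = "numeric",
        label = "character",
        evShare = "numeric",
        oriented = "logical",
        covariateName = "character"
    )
)

#' Insulation-score track
#'
#' Sliding-window insulation: s_i is the mean contact value of the w x w
#' square spanning bins (i-w..i-1) x (i+1..i+w); the reported score is
#' I_i = log2(s_i / chromosome mean of s). Defined only where the full window
#' fits within the chromosome.
#'
#' @slot bins \linkS4class{GenomeBins}.
#' @slot window integer window half-width w in bins.
#' @slot raw numeric per-bin window mean s_i (NA where undefined).
#' @slot insulation numeric per-bin I_i.
#' @export
setClass("InsulationTrack",
    representation(
        bins = "GenomeBins",
        window = "integer",
        raw = "numeric",
        insulation = "numeric"
    )
)

#' Called chromatin loops
#'
#' Pixels enriched over their local neighborhoods (donut, lower-left,
#' horizontal, vertical), HiCCUPS-style, with Poisson p-values and BH q.
#' Adjacent significant pixels are clustered; one centroid per cluster is
#' flagged and constitutes the reported loop list.
#'
#' @slot pixels data.frame of significant pixels with enrichment statistics.
#' @slot nTested integer number of candidate pixels tested.
#' @slot params list of calling parameters.
#' @export
setClass("LoopSet",
    representation(pixels = "data.frame", nTested = "integer", params = "list")
)

#' Aggregate peak analysis result
#'
#' Mean observed/expected submatrix over a set of anchor pixels, and the APA
#' score: center value over the mean of the lower-left corner.
#'
#' @slot agg numeric (2W+1)^2 aggregate matrix.
#' @slot score numeric APA score.
#' @slot W integer window half-width (bins).
#' @slot corner integer corner size c (bins).
#' @slot nAnchors integer anchors used; @slot nSkipped integer anchors skipped.
#' @slot diff matrix cellwise difference to a reference aggregate (0x0 if none).
#' @slot scoreDiff numeric score difference to the reference (NA if none).
#' @export
setClass("ApaResult",
    representation(
        agg = "matrix", score = "numeric", W = "integer", corner = "integer",
        nAnchors = "integer", nSkipped = "integer",
        diff = "matrix", scoreDiff = "numeric"
    )
)

#' Stratum-adjusted correlation coefficient result
#'
#' Distance-stratified Pearson correlations between two smoothed contact
#' maps, combined with weights w_d = N_d * sd(x_d) * sd(y_d).
#'
#' @slot scc numeric genome-wide SCC.
#' @slot perChrom numeric named per-chromosome SCC.
#' @slot strata data.frame: chrom, distance (bp), r, n, w.
#' @slot h integer smoothing half-width; @slot maxDist numeric max distance bp.
#' @export
setClass("SccResult",
    representation(
        scc = "numeric", perChrom = "numeric", strata = "data.frame",
        h = "integer", maxDist = "numeric"
    )
)

#' Specification of a synthetic Hi-C cohort
#'
#' Fully determines the expected contact probability map: power-law distance
#' decay, A/B checkerboard compartments, block TADs, Gaussian-footprint loops,
#' a uniform trans fraction, and an optional group-specific locus effect.
#'
#' @slot chromLengths numeric named vector of chromosome lengths (bp).
#' @slot binSize numeric bin size (bp).
#' @slot alpha numeric decay exponent (contact probability ~ d^-alpha).
#' @slot compartments list per chromosome: character vector of per-bin "A"/"B"
#'   labels (empty list for none).
#' @slot compStrength numeric c in [0,1): same-label cells x (1+c), opposite
#'   x (1-c).
#' @slot tadBoundaries list per chromosome: strictly increasing interior
#'   boundary bin indices (1-based; a boundary at k separates bins <= k from
#'   bins > k).
#' @slot tadBoost numeric t >= 1 applied within TADs.
#' @slot loops data.frame (chrom, i, j) loop pixel bins (1-based, i < j).
#' @slot loopBoost numeric L > 1 peak factor.
#' @slot loopHalfWidth integer loop footprint half-width (bins).
#' @slot transFrac numeric fraction of total probability in trans cells.
#' @slot transBoost data.frame (chrom1, chrom2, factor) per-block trans boosts
#'   (rearrangement scenario; zero rows for none).
#' @slot groupEffect list with chrom, startBin, endBin, factor (empty if none).
#' @export
setClass("SyntheticSpec",
    representation(
        chromLengths = "numeric", binSize = "numeric", alpha = "numeric",
        compartments = "list", compStrength = "numeric",
        tadBoundaries = "list", tadBoost = "numeric",
        loops = "data.frame", loopBoost = "numeric", loopHalfWidth = "integer",
        transFrac = "numeric", transBoost = "data.frame", groupEffect = "list"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- NULL
    if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
        msg <- c(msg, "chromLengths must be a named vector of positive lengths")
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@compStrength < 0 || object@compStrength >= 1)
        msg <- c(msg, "compartment strength must lie in [0, 1)")
    if (object@tadBoost < 1) msg <- c(msg, "tadBoost must be >= 1")
    if (object@loopBoost <= 0) msg <- c(msg, "loopBoost must be positive")
    if (object@transFrac < 0 || object@transFrac >= 1)
        msg <- c(msg, "transFrac must lie in [0, 1)")
    nb <- ceiling(object@chromLengths / object@binSize)
    for (ch in names(object@tadBoundaries)) {
        b <- object@tadBoundaries[[ch]]
        if (length(b) && (is.unsorted(b, strictly = TRUE) ||
                          any(b < 1) || any(b >= nb[ch])))
            msg <- c(msg, sprintf("TAD boundaries for %s must be strictly increasing interior bins", ch))
    }
    if (nrow(object@loops)) {
        ok <- object@loops$chrom %in% names(object@chromLengths) &
            object@loops$i >= 1 & object@loops$j > object@loops$i &
            object@loops$j <= nb[object@loops$chrom]
        if (!all(ok)) msg <- c(msg, "loop pixels out of range")
    }
    if (length(object@groupEffect)) {
        ge <- object@groupEffect
        if (!all(c("chrom", "startBin", "endBin", "factor") %in% names(ge)) ||
            !ge$chrom %in% names(object@chromLengths) ||
            ge$startBin < 1 || ge$endBin < ge$startBin ||
            ge$endBin > nb[ge$chrom] || ge$factor <= 0)
            msg <- c(msg, "invalid groupEffect")
    }
    if (is.null(msg)) TRUE else msg
})

#' Expected probability map for a synthetic cohort
#'
#' Genome-wide symmetric matrix of cell probabilities; the upper triangle
#' (including the diagonal) sums to 1 and is the sampling distribution.
#'
#' @slot prob numeric symmetric matrix.
#' @slot bins \linkS4class{GenomeBins}.
#' @slot spec the generating \linkS4class{SyntheticSpec}.
#' @export
setClass("ProbabilityMap",
    representation(prob = "matrix", bins = "GenomeBins", spec = "SyntheticSpec")
)

setValidity("ProbabilityMap", function(object) {
    p <- object@prob
    if (any(p < 0)) return("negative probabilities")
    tot <- sum(p[upper.tri(p, diag = TRUE)])
    if (abs(tot - 1) > 1e-8) return("upper-triangle probabilities must sum to 1")
    if (max(abs(p - t(p))) > 1e-12) return("probability map must be symmetric")
    TRUE
})

#' Planted ground truth of a synthetic cohort
#'
#' @slot labels list per chromosome of planted A/B labels.
#' @slot boundaries list per chromosome of planted TAD boundary bins.
#' @slot loopPixels data.frame of planted loop pixels.
#' @slot groupEffect list describing the planted group effect (empty if none).
#' @export
setClass("PlantedTruth",
    representation(
        labels = "list", boundaries = "list",
        loopPixels = "data.frame", groupEffect = "list"
    )
)
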
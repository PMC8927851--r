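#' Read a pipeline run configuration
#'
#' YAML with: \code{samples} (list of name/file/group), \code{chromSizes},
#' optional \code{genes} (BED), \code{reference} (sample name, default the
#' first sample), \code{outdir}, \code{seed}, and parameter blocks
#' \code{binSizes}, \code{analysisBinSize}, \code{compartmentBinSize},
#' \code{resolution}, \code{ice}, \code{insulation}, \code{loops},
#' \code{apa}, \code{scc}, \code{diff}. Missing values take the package
#' defaults (the standard bin-size ladder 20 kb/40 kb/150 kb/500 kb/1 Mb,
#' ICE at maxIter 100 / lowPct 0.02 / eps 0.1, and so on).
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as from YAML).
#' @export
validateRunConfig <- function(cfg) {
    stopifnot(!is.null(cfg$samples), !is.null(cfg$chromSizes),
              !is.null(cfg$outdir))
    sheet <- do.call(rbind, lapply(cfg$samples, function(s)
        data.frame(sample = s$name, file = s$file,
                   group = if (is.null(s$group)) NA_character_ else s$group)))
    if (anyDuplicated(sheet$sample)) stop("sample names must be unique")
    if (!all(file.exists(sheet$file)))
        stop("missing valid-pairs file(s): ",
             paste(sheet$file[!file.exists(sheet$file)], collapse = ", "))
    if (!file.exists(cfg$chromSizes))
        stop("missing chrom.sizes file: ", cfg$chromSizes)
    cfg$sheet <- sheet
    if (is.null(cfg$reference)) cfg$reference <- sheet$sample[1]
    if (!cfg$reference %in% sheet$sample)
        stop("reference sample not in sheet: ", cfg$reference)
    dflt <- function(x, d) if (is.null(x)) d else x
    cfg$binSizes <- dflt(cfg$binSizes, c(2e4, 4e4, 1.5e5, 5e5, 1e6))
    cfg$analysisBinSize <- dflt(cfg$analysisBinSize, min(cfg$binSizes))
    cfg$compartmentBinSize <- dflt(cfg$compartmentBinSize, 1e5)
    cfg$resolution <- utils::modifyList(
        list(candidates = c(1e6, 5e5, 2e5, 1e5, 4e4, 2e4, 1e4, 5e3, 1e3),
             threshold = 1000, percentile = 0.8), dflt(cfg$resolution, list()))
    cfg$ice <- utils::modifyList(
        list(maxIter = 100, lowPct = 0.02, highPct = 0, eps = 0.1),
        dflt(cfg$ice, list()))
    cfg$insulation <- utils::modifyList(
        list(w = 25, strengthMin = 0.1, minTad = 3),
        dflt(cfg$insulation, list()))
    cfg$loops <- utils::modifyList(
        list(dMin = 2, dMax = 2e6, donutR = 5, innerR = 2, foldMin = 1.5,
             qMax = 0.1), dflt(cfg$loops, list()))
    cfg$apa <- utils::modifyList(list(W = 5, corner = 3),
                                 dflt(cfg$apa, list()))
    cfg$scc <- utils::modifyList(list(h = 2, maxDist = 5e6),
                                 dflt(cfg$scc, list()))
    cfg$diff <- utils::modifyList(list(span = 0.3, cycles = 3, qSig = 0.05),
                                  dflt(cfg$diff, list()))
    cfg$seed <- dflt(cfg$seed, 1)
    cfg
}

stageBanner <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full comparative Hi-C workflow
#'
#' Per sample: parse valid pairs, determine map resolution, bin at all
#' configured sizes, ICE-balance the analysis-resolution matrix, compute
#' decay/RCP curves with the LOWESS expected model, call A/B compartments at
#' the compartment resolution, compute insulation and TADs, and call loops.
#' Across samples: pairwise SCC matrix, delta matrices against the reference,
#' APA on the reference sample's anchors with difference-to-reference, group
#' compartment-switch detection, and joint normalization with exact-test
#' differential interaction detection. All numeric stages are deterministic
#' given the input files, so a re-run reproduces outputs byte-identically.
#'
#' @param config a config list (\code{\link{readRunConfig}}) or YAML path.
#' @param writeFiles write standard-format outputs and a manifest under
#'   \code{config$outdir} (default TRUE).
#' @return invisibly, a results list (per-sample objects, comparison tables,
#'   and the JSON-ready run report).
#' @export
runPipeline <- function(config, writeFiles = TRUE) {
    if (is.character(config)) config <- readRunConfig(config)
    else config <- validateRunConfig(config)
    sheet <- config$sheet
    genomeB <- readChromSizes(config$chromSizes, config$analysisBinSize)
    lens <- setNames(genomeB@chromLengths, genomeB@chromNames)
    res <- list(config = config, samples = list())
    for (k in seq_len(nrow(sheet))) {
        name <- sheet$sample[k]
        stageBanner("parse", "%s: reading %s", name, sheet$file[k])
        pairs <- readValidPairs(sheet$file[k], genomeB)
        stageBanner("resolution", "%s: %d pairs", name, nPairs(pairs))
        rr <- mapResolution(pairs, lens,
                            candidateSizes = config$resolution$candidates,
                            depthThreshold = config$resolution$threshold,
                            percentile = config$resolution$percentile)
        bsz <- setNames(config$binSizes,
                        format(config$binSizes, scientific = FALSE,
                               trim = TRUE))
        mats <- lapply(bsz, function(B) binContacts(pairs, lens, B))
        stageBanner("balance", "%s: ICE at %g bp (maxIter=%d, eps=%g)", name,
                    config$analysisBinSize, config$ice$maxIter,
                    config$ice$eps)
        raw <- binContacts(pairs, lens, config$analysisBinSize)
        iced <- iceNormalize(raw, maxIter = config$ice$maxIter,
                             lowPct = config$ice$lowPct,
                             highPct = config$ice$highPct,
                             eps = config$ice$eps)
        stageBanner("decay", "%s: Ps/RCP curves", name)
        ps <- lowessExpected(decayCurve(iced, stratumBp = 1e6))
        oeA <- observedOverExpected(iced)
        stageBanner("compartments", "%s: eigenvector at %g bp", name,
                    config$compartmentBinSize)
        rawC <- binContacts(pairs, lens, config$compartmentBinSize)
        icedC <- iceNormalize(rawC, maxIter = config$ice$maxIter,
                              lowPct = config$ice$lowPct,
                              highPct = config$ice$highPct,
                              eps = config$ice$eps)
        comp <- compartmentEigenvector(observedOverExpected(icedC))
        stageBanner("insulation", "%s: w=%d bins", name, config$insulation$w)
        ins <- insulationScore(iced, w = config$insulation$w)
        tads <- callTads(ins, strengthMin = config$insulation$strengthMin,
                         minTad = config$insulation$minTad)
        stageBanner("loops", "%s", name)
        loops <- callLoops(iced, dMin = config$loops$dMin,
                           dMax = config$loops$dMax,
                           donutR = config$loops$donutR,
                           innerR = config$loops$innerR,
                           foldMin = config$loops$foldMin,
                           qMax = config$loops$qMax)
        res$samples[[name]] <- list(
            pairs = pairs, resolution = rr, matrices = mats, raw = raw,
            iced = iced,
            decay = ps, oe = oeA, compartments = comp, insulation = ins,
            tads = tads, loops = loops)
    }
    # orientation: gene density when provided, otherwise the reference
    # sample's eigenvector serves as the shared covariate
    refName <- config$reference
    if (!is.null(config$genes)) {
        covC <- geneDensity(res$samples[[1]]$compartments@bins, config$genes)
        covName <- "geneDensity"
    } else {
        covC <- res$samples[[refName]]$compartments@e1
        covName <- paste0("E1:", refName)
    }
    for (name in names(res$samples))
        res$samples[[name]]$compartments <-
            orientCompartments(res$samples[[name]]$compartments, covC, covName)
    nS <- length(res$samples)
    groups <- sheet$group
    twoGroups <- length(unique(groups[!is.na(groups)])) == 2
    if (nS >= 2) {
        stageBanner("scc", "pairwise SCC (h=%d, D<=%g)", config$scc$h,
                    config$scc$maxDist)
        res$scc <- sccMatrix(lapply(res$samples, `[[`, "raw"),
                             h = config$scc$h, maxDist = config$scc$maxDist)
        stageBanner("delta", "delta matrices vs %s", refName)
        res$delta <- lapply(res$samples[names(res$samples) != refName],
                            function(s) deltaMatrix(s$iced,
                                res$samples[[refName]]$iced))
        stageBanner("apa", "anchors from %s", refName)
        anchors <- loopPixels(res$samples[[refName]]$loops)[, c("chrom", "i", "j")]
        if (!nrow(anchors))
            anchors <- boundaryAnchors(res$samples[[refName]]$tads$boundaries,
                                       minSep = 2 * config$apa$W + 1,
                                       maxSep = floor(config$loops$dMax /
                                                      config$analysisBinSize))
        if (nrow(anchors)) {
            apas <- lapply(res$samples, function(s)
                tryCatch(apa(s$oe, anchors, W = config$apa$W,
                             corner = config$apa$corner),
                         error = function(e) NULL))
            if (!is.null(apas[[refName]]))
                apas <- lapply(apas, function(a)
                    if (is.null(a)) NULL else apaVsReference(a, apas[[refName]]))
            res$apa <- apas
        } else stageBanner("apa", "no usable anchors; skipped")
    } else stageBanner("compare", "single sample: comparison stages skipped")
    if (twoGroups) {
        gl <- unique(groups[!is.na(groups)])
        i1 <- which(groups == gl[1]); i2 <- which(groups == gl[2])
        stageBanner("switches", "%s vs %s", gl[1], gl[2])
        res$switches <- detectSwitches(
            lapply(res$samples[i1], `[[`, "compartments"),
            lapply(res$samples[i2], `[[`, "compartments"),
            genes = config$genes)
        stageBanner("diff", "fastlo + exact test")
        # the count-based comparison operates on raw binned counts; its own
        # loess step does the cross-sample normalization
        norm <- jointNormalize(lapply(res$samples, `[[`, "raw"),
                               span = config$diff$span,
                               cycles = config$diff$cycles)
        res$diff <- exactTestDiff(norm, groups)
    } else stageBanner("compare", "no two-group design: switch/diff skipped")
    res$report <- buildRunReport(res)
    if (writeFiles) res$manifest <- writeOutputs(res, config$outdir)
    invisible(res)
}

buildRunReport <- function(res) {
    rep <- list(samples = lapply(res$samples, function(s) list(
        nPairs = nPairs(s$pairs),
        finestResolution = s$resolution$finestAchieved,
        maskedBins = sum(maskedBins(s$iced)),
        nTads = nrow(s$tads$tads),
        nBoundaries = nrow(s$tads$boundaries),
        nLoops = nrow(loopPixels(s$loops)))))
    if (!is.null(res$scc)) rep$scc <- as.data.frame(res$scc)
    if (!is.null(res$apa))
        rep$apaScores <- lapply(res$apa, function(a)
            if (is.null(a)) NA else list(score = apaScore(a),
                                         scoreDiff = a@scoreDiff))
    if (!is.null(res$switches))
        rep$switches <- list(nRegions = length(res$switches$regions),
                             nGenes = res$switches$nGenes)
    if (!is.null(res$diff)) {
        d <- res$diff
        qs <- d$q < 0.05 & !is.na(d$q)
        top <- d[order(d$q, d$p), ][seq_len(min(10, nrow(d))), ]
        rep$diff <- list(nTested = nrow(d), nSignificant = sum(qs),
                         top = top[, c("chrom", "i", "j", "distance", "M",
                                       "p", "q")])
    }
    rep
}

#' Write pipeline outputs and a checksum manifest
#'
#' Emits the standard-format outputs of a completed run — bedGraph (E1,
#' insulation), BED (TADs, boundaries, A/B segments, switch regions), BEDPE
#' and washU longrange (loops), TSV (decay curves, SCC, DiffTable), triplet
#' matrices with bins tables, JSON (resolution reports, run report) — and a
#' manifest listing every file with its md5 checksum.
#'
#' @param res results list from \code{\link{runPipeline}}.
#' @param outdir output directory.
#' @return data.frame manifest (file, md5).
#' @export
writeOutputs <- function(res, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    emit <- function(f) { files <<- c(files, f); f }
    for (name in names(res$samples)) {
        s <- res$samples[[name]]
        d <- file.path(outdir, name)
        dir.create(d, showWarnings = FALSE)
        for (B in names(s$matrices))
            writeTripletMatrix(s$matrices[[B]],
                emit(file.path(d, sprintf("matrix_%s.tsv", B))),
                emit(file.path(d, sprintf("bins_%s.tsv", B))))
        writeResolutionReport(s$resolution,
                              emit(file.path(d, "resolution.json")))
        writeDecayCurve(s$decay, emit(file.path(d, "decay.tsv")))
        cb <- s$compartments@bins
        writeBedGraph(cb, s$compartments@e1,
                      emit(file.path(d, "compartments_E1.bedGraph")),
                      paste0(name, " E1"))
        writeBed(compartmentSegments(s$compartments),
                 emit(file.path(d, "compartments_AB.bed")))
        writeBedGraph(s$insulation@bins, s$insulation@insulation,
                      emit(file.path(d, "insulation.bedGraph")),
                      paste0(name, " insulation"))
        bd <- s$tads$boundaries
        writeBed(data.frame(chrom = bd$chrom, start = bd$pos,
                            end = bd$pos + s$insulation@bins@binSize,
                            name = sprintf("boundary_%.3f", bd$strength)),
                 emit(file.path(d, "boundaries.bed")))
        writeBed(s$tads$tads[, c("chrom", "start", "end")],
                 emit(file.path(d, "tads.bed")))
        writeLoopsBedpe(s$loops, s$iced@bins,
                        emit(file.path(d, "loops.bedpe")))
        writeLongrange(s$loops, s$iced@bins,
                       emit(file.path(d, "loops.longrange.txt")))
    }
    if (!is.null(res$scc))
        writeHeatTable(res$scc, emit(file.path(outdir, "scc_matrix.tsv")))
    if (!is.null(res$switches)) {
        sw <- res$switches$regions
        writeBed(data.frame(chrom = as.character(GenomicRanges::seqnames(sw)),
                            start = GenomicRanges::start(sw) - 1,
                            end = GenomicRanges::end(sw),
                            name = sw$direction),
                 emit(file.path(outdir, "switch_regions.bed")))
    }
    if (!is.null(res$diff))
        writeDiffTable(res$diff, res$samples[[1]]$iced@bins,
                       emit(file.path(outdir, "diff_table.tsv")),
                       qSig = res$config$diff$qSig)
    if (!is.null(res$apa)) for (name in names(res$apa)) {
        a <- res$apa[[name]]
        if (is.null(a)) next
        f <- emit(file.path(outdir, sprintf("apa_%s.tsv", name)))
        data.table::fwrite(as.data.frame(a@agg), f, sep = "\t",
                           col.names = FALSE)
    }
    jsonlite::write_json(res$report, emit(file.path(outdir, "report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)))
    data.table::fwrite(manifest, file.path(outdir, "MANIFEST.tsv"),
                       sep = "\t")
    manifest
}
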
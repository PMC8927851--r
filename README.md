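# HiCohort

Comparative Hi-C analysis for small cohorts — from valid contact pairs to
balanced matrices, map resolution, distance-decay curves, A/B compartments
with group switch detection, insulation-score TADs, loop calling with
aggregate peak analysis, stratum-adjusted reproducibility, and exact-test
differential chromatin interactions — with a synthetic contact-map generator
that plants fully known structure so every stage can be validated against
ground truth.

## Who this is for

Studies that profile the 3D genome of a handful of samples split into groups
(e.g. patients vs. controls, primary cells vs. a cell line) and need the
standard comparative toolkit in one reproducible, scriptable package:
characterize each map, quantify reproducibility, and localize group
differences. All containers are S4 classes with accessors; every stage is an
exported function; a YAML-driven pipeline sequences the whole workflow
deterministically.

## The methods in brief

* **Binning and ICE.** Pairs are binned into a genome-wide symmetric count
  matrix; iterative correction divides each row/column by its relative
  coverage s_i/mean(s) until max|s_i/mean(s) − 1| < ε (defaults: 100
  iterations, ε = 0.1, lowest 2% of bins masked). Bias vector b_i recovers
  raw counts as b_i·b_j·normalized.
* **Map resolution.** Per candidate bin size, bins are sorted by coverage
  (pair ends) in descending order; a size is achieved when the depth at the
  80th-percentile position reaches 1000.
* **Decay / RCP.** P(s) = mean contact per 1 Mb distance stratum; expected
  via LOWESS of log(observed) on log(distance); RCP = per-chromosome curve
  normalized to unit sum.
* **Compartments.** E1 = leading eigenvector of the Pearson correlation of
  the O/E map, oriented by gene density; A ⇔ E1 > 0. Group switches require
  within-group unanimity over runs of ≥ 3 bins.
* **Insulation / TADs.** I_i = log2 of the w×w cross-window mean over the
  chromosome mean (w = 25 bins); boundaries are strength-filtered local
  minima; TADs the intervals between them.
* **Loops / APA.** Donut, lower-left, horizontal and vertical neighborhoods
  define local Poisson expectations per pixel; BH across pixels; APA score =
  center of the aggregate O/E submatrix over its lower-left corner.
* **SCC.** Distance-stratified Pearson correlations of 2D-mean-filtered maps
  (h = 2, D ≤ 5 Mb) combined with weights w_d = N_d·sd(x_d)·sd(y_d).
* **Differential interactions.** Cyclic fast-loess normalization of
  log2(IF + 0.5) against log distance, then a conditional exact test
  (negative binomial with per-stratum moment dispersion; binomial split when
  dispersion vanishes) with BH adjustment; M and D exported for MD plots.

See `vignettes/hicohort-methods.Rmd` for assumptions, parameter defaults and
design choices.

## Worked example

Plant two loops on a 10 Mb toy chromosome, sample 2 million pairs, and run
the single-sample stages:

```r
library(HiCohort)

spec <- syntheticSpec(
    chromLengths = c(chrS = 1e7), binSize = 4e4,
    loops = data.frame(chrom = "chrS", i = c(60L, 140L), j = c(95L, 170L)),
    loopBoost = 5, tadBoundaries = list(), tadBoost = 1)
pairs <- sampleContacts(buildProbabilityMap(spec), 2e6, seed = 1)
cm <- iceNormalize(binContacts(pairs, c(chrS = 1e7), 4e4))
cm
#> ContactMatrix [iced]: 250 bins @ 40,000 bp, 2e+06 pairs, 5 masked bin(s)

mapResolution(pairs, c(chrS = 1e7), candidateSizes = c(1e6, 1e5, 4e4, 1e4))
#> ResolutionReport (threshold 1000 at the 80th-percentile bin, ends coverage)
#>  binSize nBins depth75 depth80 depth90 decisionDepth fracAbove achieved
#>    1e+06    10  397470  397470  355699        397470         1     TRUE
#>    1e+05   100   39453   38749   36689         38749         1     TRUE
#>    4e+04   250   15779   15435   14653         15435         1     TRUE
#>    1e+04  1000    3924    3862    3651          3862         1     TRUE
#> Finest achieved bin size: 10,000 bp

loops <- callLoops(cm)
loopPixels(loops)[, c("chrom", "i", "j", "fold_donut", "q_donut")]
#>  chrom   i   j fold_donut      q_donut
#>   chrS  60  95   4.016302 1.782827e-44
#>   chrS 140 170   4.884443 1.008015e-73

apa(observedOverExpected(cm), loopPixels(loops))
#> ApaResult: W=5, 2 anchor(s) (0 skipped), score 4.641
```

Both planted loops (and nothing else) are recovered out of 10,731 tested
pixels; the APA score ≈ the planted boost of 5. The depth supports a 10 kb
map (every candidate's 80th-percentile depth clears 1000, and at 10 kb all
bins exceed it).

TAD calling on the package's reference system (eight planted domains,
within-domain boost 2) recovers every interior boundary within one bin —
planted at bins 31, 62, 94, 125, 156, 188, 219:

```r
spec2 <- syntheticSpec()   # 10 Mb, 40 kb bins, alpha = 1, 8 TADs
pairs2 <- sampleContacts(buildProbabilityMap(spec2), 2e6, seed = 4)
cm2 <- iceNormalize(binContacts(pairs2, c(chrS = 1e7), 4e4))
head(callTads(insulationScore(cm2))$boundaries[, c("chrom", "bin", "pos", "strength")], 4)
#>  chrom bin     pos  strength
#>   chrS  32 1240000 0.5896555
#>   chrS  62 2440000 0.6330457
#>   chrS  95 3760000 0.6627370
#>   chrS 126 5000000 0.6687506

# reproducibility of two half-depth technical replicates
rep1 <- binContacts(thinReplicate(pairs2, 0.5, seed = 5), c(chrS = 1e7), 4e4)
rep2 <- binContacts(thinReplicate(pairs2, 0.5, seed = 6), c(chrS = 1e7), 4e4)
scc(rep1, rep2)
#> SccResult: SCC = 0.9896 (h=2, D<=5e+06 bp, 125 strata)
```

For a full cohort analysis (groups, switches, APA vs. a reference sample,
differential test) write a YAML config and call `runPipeline("config.yaml")`,
or use the command-line wrapper `inst/scripts/hicohort.R` (subcommands
`simulate`, `bin`, `balance`, `resolution`, `decay`, `compartments`,
`insulation`, `loops`, `apa`, `scc`, `run-all`).

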
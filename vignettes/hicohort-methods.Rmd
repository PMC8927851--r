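---
title: "Comparative Hi-C analysis with HiCohort: models, parameters and design choices"
author: "HiCohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hi-C analysis with HiCohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HiCohort)
```

# Scope

HiCohort implements the comparative Hi-C workflow used to characterize the 3D
genomes of small sample cohorts (for example a handful of primary-cell donors
split into a patient and a control group, plus cell-line references): from
valid contact pairs to balanced matrices, map-resolution determination,
distance-decay curves, A/B compartments with group switch detection,
insulation-score TADs, local-enrichment loop calling with aggregate peak
analysis, stratum-adjusted correlation for reproducibility, and exact-test
differential interaction detection. A synthetic contact-map generator with
fully known planted structure stands in for raw sequencing data, so that every
downstream stage can be validated against ground truth.

This vignette is the package's own account of the methods: the models and
their assumptions, the tunable parameters with their defaults and units, the
numerical choices, and what the synthetic validation does and does not show
about real data.

# The synthetic generator

The generator draws valid pairs from an explicit expected probability map
built multiplicatively from four structural layers on top of a power-law
distance decay:

* **Decay.** A cis cell at distance $d$ bins carries weight
  $\max(d,1)^{-\alpha}$. The default exponent $\alpha = 1$ is the classical
  fractal-globule-like slope observed in mammalian Hi-C at the megabase scale.
* **TADs.** Cells whose two bins share a domain are multiplied by a boost
  $t \ge 1$ (default 2). Domains are delimited by an ordered list of interior
  boundary bins; the default layout is eight equal domains per chromosome.
* **Compartments.** With per-bin A/B labels, same-label cells are multiplied
  by $(1+c)$ and opposite-label cells by $(1-c)$, $c \in [0,1)$. The
  checkerboard used in validation has $c = 0.4$.
* **Loops.** Each loop pixel $(i,j)$ applies a Gaussian-decayed boost
  $1 + (L-1)\exp\{-(\delta_i^2 + \delta_j^2)/2\sigma^2\}$ over a
  $(2h+1)^2$ footprint with $\sigma = \max(h,1)/2$ (defaults $L = 5$,
  $h = 1$), a simple differentiable ground truth for aggregate peak analysis.

Trans cells share a single uniform fraction of the total probability (default
0.15 for multi-chromosome genomes), mimicking the observed dominance of cis
contacts without modelling translocations; per-block trans boosts support a
rearrangement scenario in which one chromosome pair shows a strengthened
trans block. An optional *group effect* multiplies the expected map of one
group by a constant factor at all cells within a locus interval, emulating a
group-specific structural difference at a single locus. The map is normalized
so its upper triangle sums to one, and $N$ pairs are drawn multinomially;
ends are placed uniformly within bins with uniform strands. Replicates are
emulated by binomial thinning (each record kept independently with
probability $p$). Seeds are explicit inputs everywhere and the global RNG
state is never touched.

The reference toy system used throughout the tests is one 10 Mb chromosome at
40 kb bins (250 bins) with $\alpha = 1$, eight planted TADs at $t = 2$ and
$2\times10^6$ pairs — deep enough that boundary recovery and replicate
reproducibility are limited by the method, not the noise floor, while staying
desk-scale. Smaller problems (a 5 Mb chromosome at 100 kb bins with
$10^5$–$5\times10^5$ pairs per sample) are used for the cohort-level
machinery.

What the generator does *not* emulate: restriction-fragment granularity and
ligation-artifact classes, sequence-driven bias (GC, mappability), nested or
hierarchical domains, polymer physics, and copy-number variation. Passing the
planted-truth tests therefore shows that each algorithm recovers the
structure it is designed for at realistic depth; it does not certify
performance on artifacts the generator omits.

# Binning, balancing and resolution

Valid pairs follow the common seven-column tab-separated dialect (read id,
chromosome/position/strand for both ends; extra columns ignored). Bins are
0-based half-open windows of width $B$; each pair increments one cell and cis
matrices are symmetrized. Matrix totals are conserved exactly.

**ICE balancing.** The matrix is corrected iteratively: at each step every
row and column is divided by its relative coverage $s_i/\bar{s}$, until
$\max_i |s_i/\bar{s} - 1| < \varepsilon$ or the iteration budget is reached.
The accumulated divisors form the bias vector $b_i$, so raw counts are
recoverable as $b_i b_j \times$ the balanced value. Defaults follow the
standard Hi-C processing configuration: at most 100 iterations,
$\varepsilon = 0.1$, and masking of the 2% lowest-coverage bins
(`lowPct = 0.02`, `highPct = 0`). Zero-coverage bins are always masked. On a
doubly balanced matrix the procedure is the identity; a constructed-bias
matrix $\mathrm{diag}(b)\,T\,\mathrm{diag}(b)$ is recovered proportional to
$T$ to $10^{-6}$ at tight tolerance.

One practical caveat observed at toy scale: because edge bins have fewer
cells over which to spread their (equalized) row sum, balancing inflates
their diagonal entries. Signed difference ("delta") matrices between
balanced toy maps are therefore dominated by this edge artifact rather than
by biology; the delta-localization validation consequently runs on
depth-scaled raw matrices, and delta maps of balanced matrices should be read
away from the first and last bins of a chromosome.

**Map resolution.** For each candidate bin size (1 Mb down to 1 kb), per-bin
coverage is computed, bins are sorted by coverage in descending order, and
the depth at the 75th-, 80th- and 90th-percentile positions is read off. A
bin size is *achieved* when the depth at the 80th-percentile position reaches
the threshold (default 1000); the finest achieved size is the map
resolution. Two interpretations were open here: coverage counts *pair ends*
(each valid pair contributes two) rather than midpoints, matching read-depth
intuition, and the percentile positions are taken on the full sorted
coverage vector. Both choices are recorded in the report (all three
percentile depths are kept inspectable) and the end/midpoint convention is
switchable.

# Distance decay and observed/expected

The contact probability curve $P(s)$ is the mean contact value per genomic
distance stratum over all unmasked cis cells, with a default stratum width of
1 Mb (distances 1 Mb, 2 Mb, ...); the diagonal forms its own stratum. The
relative contact probability (RCP) is the per-chromosome curve normalized to
unit sum over positive-distance strata — normalization is exact, enabling
cross-sample overlay. The expected model is a LOWESS fit of
$\log(\text{observed})$ on $\log(\text{distance})$ (span $f = 0.3$, two
robustifying iterations; the span is exposed). Fitting in log space keeps
expected values strictly positive; with fewer than four usable strata the
observed values serve as expected, with a warning. Per-chromosome RCP was
chosen over genome-wide normalization because the curves are compared per
chromosome across samples.

The observed/expected (O/E) transform divides each cis cell by the expected
value at its distance. By default the expected is the matrix's own
mean-at-distance (per-bin-distance strata), the classical convention under
which O/E row means are 1 for structureless input; the smoothed LOWESS model
can be passed instead. O/E is undefined (NA) on masked cells, zero-expected
cells and all trans cells.

# Compartments

Per chromosome, the Pearson correlation matrix of the O/E columns (unmasked,
non-degenerate bins) is eigendecomposed and the eigenvector of the largest
eigenvalue (E1) taken; its per-chromosome explained-variance share is
reported as a confidence signal (structureless maps give a small share,
planted checkerboards a large one). The sign of an eigenvector is arbitrary,
so orientation uses a covariate: E1 is negated when its correlation with the
covariate is negative, and bins are labelled A where $E1 > 0$, B where
$E1 < 0$. Gene density (genes per bin from a BED file) is the default
covariate because the active A compartment is gene-rich and gene intervals
are available even for synthetic genomes where GC content is meaningless; in
the pipeline, samples fall back to the reference sample's E1 as covariate
when no gene file is configured, which enforces a consistent (if unanchored)
orientation across samples.

**Switch detection.** A bin switches between groups when *every* sample of
group 1 carries one sign and *every* sample of group 2 the opposite sign —
within-group unanimity, the natural reading for a 2-vs-2 design where any
within-group disagreement makes a call unreliable. Runs of at least
`minRun = 3` switching bins merge into regions, suppressing single-bin
flicker; genes overlapping a region by at least 1 bp are reported. Both
knobs are configurable; the overlap rule (any overlap, no flanking window)
is the documented choice for gene annotation.

# Insulation and TADs

The insulation score of bin $i$ is the mean contact value $s_i$ of the
$w \times w$ square spanning bins $(i-w \ldots i-1) \times (i+1 \ldots i+w)$,
reported as $I_i = \log_2(s_i / \overline{s})$ against the chromosome mean —
a log-ratio form invariant to global scaling whose natural-scale mean is 1.
The window half-width defaults to $w = 25$ bins (1 Mb at 40 kb bins, the
scale at which mammalian TAD boundaries insulate); it is exposed in the
configuration. $I$ is defined only where the full window fits inside the
chromosome; windows with more than half their cells masked give NA rather
than biased means.

Boundaries are local minima of $I$ whose *strength* — the mean of the two
flanking local maxima minus the minimum — reaches 0.1 (Crane-style contrast;
the threshold is a parameter). TADs are the intervals between consecutive
boundaries of at least 3 bins. On the reference toy system all seven
interior boundaries are recovered within one bin with no spurious calls at
defaults. Nested/hierarchical domains and clustering-based domain finders
are out of scope.

# Loops and aggregate peak analysis

Loop calling is a single-resolution simplification of the local-neighborhood
enrichment approach: every candidate cis pixel within the distance band
(default 2 bins to 2 Mb) is compared against four neighborhoods on the
balanced matrix — donut (ring between Chebyshev radii 2 and 5, excluding the
pixel's row and column), lower-left quadrant, horizontal and vertical
stripes. Each neighborhood's local expected value is
$\lambda = (\text{neighborhood observed}/\text{neighborhood expected})
\times \text{pixel expected}$, mapped to raw-count scale through the ICE
biases for an upper-tail Poisson test. p-values are BH-adjusted across all
tested pixels (rather than the original lambda-chunked FDR, and without
multi-resolution merging — the contract here is planted-truth recovery, and
both simplifications are deliberate). A loop pixel must reach $q \le 0.1$
for donut *and* lower-left and fold $\ge 1.5$ against all four
neighborhoods; touching significant pixels are clustered (8-connectivity)
and each cluster's most donut-enriched pixel is the reported loop. On null
(decay-only) maps the caller returns essentially nothing, and planted
$L = 5$ loops are recovered at $\ge 80\%$ within one bin.

APA averages the $(2W+1)^2$ O/E submatrices centered on a set of anchors
(default $W = 5$); the score is the center value over the mean of the
$3\times3$ lower-left corner (towards the diagonal). Anchors closer than
$2W$ bins to the diagonal or to a matrix edge are skipped and counted.
Cohort comparison follows the reference-sample convention: one sample's
anchors (its loop calls, or pairs of its TAD boundaries when it has no
loops — both are supported since either reading is defensible) are applied
to every sample, and each aggregate is reported as a cellwise difference to
the reference's. On planted loops the score tracks the boost within 20%;
on null anchors it concentrates at 1.

# Reproducibility and differential interactions

**SCC.** Both maps are smoothed with a 2D mean filter of half-width
$h = 2$ bins, cis cells are stratified by distance up to $D = 5$ Mb, and the
per-stratum Pearson correlations $r_d$ are combined with weights
$w_d = N_d \, \mathrm{sd}(x_d) \, \mathrm{sd}(y_d)$ — the established
stratum-adjusted weighting. Self-comparison gives exactly 1, the measure is
symmetric and invariant to positive scaling of either matrix, and
within-stratum permutation destroys it. Because the weights concentrate on
the contact-rich near-diagonal strata, even a single strong localized group
difference visibly depresses between-group SCC while within-group values
stay near 1 — the qualitative pattern expected between divergent cell types.

**Joint normalization and exact test.** The count-based comparison operates
on *raw* binned counts: balancing redistributes counts under the
equal-visibility constraint and was observed to create spurious
opposite-signed differences bordering a planted locus effect, and the exact
test needs count-scale data. Fast loess proceeds cyclically (3 cycles): per
sample, $M = \log_2(\mathrm{IF}+0.5)$ minus the across-sample mean is
regressed on *log* genomic distance with LOWESS (span 0.3) and the fitted
trend subtracted; log distance is used because distance-dependent biases are
smooth on that scale (on a constructed monotone bias the residual trend is
below 0.01 everywhere, versus up to 0.09 in the sparse far-distance tail
with a linear-distance covariate). Totals are then rescaled to the mean of
the original depths.

The differential test conditions on each pixel's total: group sums are
modelled as negative binomial with a per-distance-stratum dispersion
estimated by the method of moments across samples, reducing to a binomial
split of the total when the dispersion vanishes; the two-sided p-value sums
all outcome probabilities at most as likely as the observed split, followed
by BH adjustment (pixels with zero total are excluded; identical test
configurations share one computation). This is a deliberate simplification
of the full normalization/dispersion machinery of dedicated multi-sample
packages; its contract — type-I control on null cohorts and recovery of a
planted 3-fold locus — is what the tests assert. Note that exact-test
p-values on discrete counts are conservative and lumpy by construction, so
calibration is asserted one-sidedly (the empirical rejection rate never
exceeds the nominal level) rather than as distributional uniformity. The
log-fold-change M and distance D per pixel are exported for MD-composite
plotting.

# Pipeline, determinism and problem sizes

`runPipeline()` sequences the stages over a YAML sample sheet (per sample:
parse, resolution, multi-size binning, ICE, decay/RCP, compartments,
insulation/TADs, loops; across samples: SCC matrix, delta matrices, APA with
difference-to-reference, switch detection, joint normalization and the exact
test) and writes standard formats — bedGraph, BED, BEDPE, washU longrange,
TSV, zero-based triplet matrices with bins tables, JSON reports — plus an
md5 manifest. Given fixed input files the pipeline has no stochastic stage,
so re-runs reproduce every output byte-identically; all randomness lives in
the generator, where seeds are explicit. Single-sample sheets skip the
comparison stages with a logged notice. The bin-size ladder defaults to
20 kb / 40 kb / 150 kb / 500 kb / 1 Mb; compartments default to 100 kb.

The validation suite runs the reference toy system (250 bins, $2\times10^6$
pairs) for decay, compartments, TADs, loops, APA and SCC, 500-bin matrices
for ICE convergence, and 50-bin cohorts ($10^5$–$5\times10^5$ pairs per
sample, 20 independent null cohorts) for the differential machinery — sizes
chosen so the whole suite runs on a laptop in minutes while keeping every
statistical check away from its noise floor.

# Known limitations

* Dense in-memory matrices: intended for cohort-scale analyses at tens of
  kb resolution or toy genomes, not for genome-wide 1 kb work.
* The loop caller is single-resolution and BH-based; very broad or nested
  enrichment structures are better served by the original multi-resolution
  implementations.
* The exact test assumes a common dispersion per distance stratum and
  library-size equality after joint normalization; strong copy-number
  effects would violate both.
* Compartment orientation is only as good as its covariate; without genes
  the pipeline's reference-E1 fallback yields consistent but biologically
  unanchored signs.
* The generator's planted structure is multiplicative and stationary; it
  does not model sequence-driven bias, so the balancing step is validated on
  constructed biases rather than emulated ones.
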
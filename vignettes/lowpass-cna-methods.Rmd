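---
title: "Copy-number profiling of single cells from low-pass sequencing: models and methods"
author: "lowpassCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profiling of single cells from low-pass sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowpassCNA)
library(GenomicRanges)
```

## The problem

A single cell holds ~6 pg of DNA — far too little to sequence directly — so
single-cell copy-number analysis amplifies the genome first.
Ligation-mediated PCR (LM-PCR) whole-genome amplification digests the genome
with a restriction enzyme (MseI, recognition site TTAA), ligates universal
adapters to the fragments and amplifies them. Two properties follow. First,
the amplified fragment set is a *deterministic* function of the genome: which
fragments exist, and their lengths, can be computed in silico. Second, the
representation of each genomic region depends on its local TTAA density and
on the size selection applied to the library, both of which vary with GC
content.

At low-pass coverage (a few hundred thousand reads, well below 1×) copy
number is read out from binned read depth: the genome is tiled with
fixed-size bins (500 kb by default), reads are counted per bin, counts are
corrected for GC and mappability biases and median-centered, and the
resulting ratio profile is segmented into regions of constant copy number.
Because a single cell is pure (no stromal admixture), the ratio profile can
further be placed on an *absolute* copy-number scale by estimating the
cell's main ploidy.

This package implements that full workflow — genome representation model,
counting, normalization, panel-of-normals blacklist, segmentation and CNA
calling, ploidy estimation — together with a simulation module that
generates synthetic genomes and cells with the biases the workflow assumes,
and an evaluation module (windowed ROC/AUC, specificity, profile
concordance).

## Genome representation model

`digestGenome()` scans each reference sequence for every occurrence of the
site motif and cuts at a fixed offset within it (T^TAA, `cutOffset = 1`; the
choice of offset moves fragment ends by at most 3 bp, immaterial at bin
scale, but it is fixed for reproducibility). Fragments tile each chromosome
exactly. `makeBins()` tiles chromosomes with complete fixed-size bins,
dropping a trailing partial bin so no downstream statistic needs per-bin
length corrections. `annotateBins()` adds GC fraction (N bases excluded from
the denominator; bins more than half N are masked), N fraction, and
mappability as the length-weighted mean of an interval track with missing
positions counted as zero.

Size selection is modelled by a fragment-length weight function. The true
selection density is instrument- and protocol-specific and typically
unimodal and right-skewed; the default is a log-normal density (meanlog
log(400), sdlog 0.6) supported on 50–3000 bp, and a tabulated weight
function can be supplied instead. `weightedFragmentCount()` assigns each
fragment to the bin containing its midpoint (unambiguous and
total-conserving) and accumulates its weight, giving the per-bin expected
representation against which observed counts can be compared.

## Read counting

Reads are intervals on the reference; a read overlapping several bins
increments only the bin with the longest overlap, with ties broken to the
leftmost bin (deterministic and order-free). Reads below the mapping-quality
floor (default 0), on unknown chromosomes, or entirely outside the retained
bins are discarded and tallied, so `assigned + discarded` always equals the
input. Fragment-level counting (`countReadsOnFragments()`) keeps only reads
overlapping exactly one in-silico fragment, discarding ambiguous matches.
Duplicate reads are not removed — a documented limitation; at these read
depths duplication is dominated by the amplification itself, which the
normalization absorbs.

BAM input is supported through Rsamtools (primary alignments only); a plain
BED dialect (`chrom, start, end, mapq`) lets the whole pipeline run without
alignment-format dependencies.

## Normalization

Corrections are applied in the order GC, then mappability, then median
centering.

**GC correction.** A robust LOWESS curve of count against GC is fitted and
each count is divided by the fitted value at its GC. Two refinements matter
in practice:

* The curve is fitted to per-GC-stratum *medians* (51 quantile strata by
  default) rather than to raw bins. In a heavily aberrant cell 40% or more
  of the genome can sit at non-neutral copy numbers; a direct fit absorbs
  copy number into the correction wherever copy-number states and GC strata
  are unevenly mixed, distorting entire segments by several percent. The
  stratum median tracks the modal (neutral) level as long as no stratum is
  majority-aberrant.
* The fit runs on the *log* of the stratum medians, with linear (in log
  space) extrapolation beyond the outermost stratum medians. Representation
  and amplification biases are multiplicative and near-exponential in GC;
  local linear fits in linear space leave a systematic monotone residual
  (we measured flat-cell Spearman correlations of ratio with GC around
  −0.11 to −0.16 before this change, and at most ±0.07 after).

Bins whose fitted expectation falls below 10% of the median fitted
expectation are marked unusable: at low pass such bins contain a handful of
reads, and dividing by a tiny fitted value turns shot noise into extreme
ratio outliers that later masquerade as copy-number levels.

**Mappability.** Values are divided by bin mappability, and bins below a
0.85 floor are excluded — counts in poorly mappable bins are artifactually
distorted rather than rescalable.

**Centering.** Values are divided by the median over usable bins, so a
karyotypically flat genome sits at ratio 1. The `CNProfile` container
enforces this invariant (unit median over usable bins; `NA` exactly where
unusable).

**Quality metrics.** Uniformity is the fraction of usable bins at or above
20% of the mean ratio; the coverage fraction uses 60% of the mean; DLRS
(derivative log-ratio spread) is the standard deviation of consecutive
differences of log2 ratio in genome order (chromosome-boundary pairs
excluded) divided by √2. The 3-standard-deviation outlier fraction is
reported as a diagnostic only; filtering happens through mappability and the
blacklist.

**Panel of normals.** Given normalized profiles of karyotypically normal
control cells on one bin table, the per-bin median ratio across the panel is
computed for every bin usable in more than half the panel; bins with median
strictly above 1.4 or strictly below 0.6 are flagged, and maximal runs of
adjacent flagged bins merge into blacklist regions used to filter
false-positive calls.

## Segmentation and CNA calling

The profile is segmented per chromosome by recursive binary splitting: the
split maximizing the reduction in residual sum of squares is accepted only
if the gain exceeds `penalty · σ̂² · log n`, where σ̂ is a robust noise scale
estimated genome-wide from the median absolute consecutive difference of the
ratio (divided by 0.6745·√2) and `n` is the chromosome's usable bin count.
This is a BIC-style stopping rule: one changepoint adds two parameters
(≈ 2·log n); the default `penalty = 3` rounds that up in favour of
specificity, which is the binding constraint at low pass. Splits always
leave at least `minBins` (default 3) bins on each side.

Segment mean ratios are converted to integer copy numbers as
`round(meanRatio × mainPloidy)` with ties rounded away from zero, and
classified as gain, loss or neutral relative to the main ploidy. Each
non-neutral segment is then tested against the pooled per-bin ratios of all
neutral segments genome-wide, with both a two-sample Wilcoxon rank-sum test
and a two-sample Kolmogorov–Smirnov test; a call requires both p-values
below α (default 0.01). Two-bin segments cannot reach p < 0.01 in the rank
test and are therefore never called — an intentional floor on call size.
Calls overlapping blacklist regions by strictly more than half their length
are removed. Cross-cell summaries intersect per-class call footprints into
core alterations, and report each cell's share of the core and its private
call length.

## Ploidy estimation

The normalized ratio profile determines relative copy number only; the main
ploidy scales it to absolute copy numbers. For each candidate main ploidy P
(2–8):

1. ratios of usable bins are multiplied by P and smoothed along the genome
   (running median of width 5 then running mean of width 5, per
   chromosome) — the median pass removes isolated spikes, the mean pass
   reduces residual noise, and steps survive to within the window width;
2. a Gaussian kernel density of the smoothed values is estimated with
   Silverman's rule-of-thumb bandwidth, clamped to [0.06, 0.25] copy-number
   units. The clamp is the automated counterpart of adjusting the bandwidth
   after visual inspection: the rule-of-thumb under-smooths strongly
   multimodal data (its IQR term reflects mostly the dominant mode) and
   over-smooths at high candidate ploidies (its scale term grows with P),
   while the useful range is known a priori because a correct candidate
   places modes at consecutive integers;
3. density peaks are detected by continuous-wavelet-transform ridge lines
   (Mexican-hat kernel; maxima linked coarse-to-fine; a plain local-maxima
   finder is available and agrees on clean densities). Each peak's mass is
   the density integral over its basin between flanking minima; peaks below
   2% mass are discarded as potential false positives;
4. peak positions are regressed on their rounded integer copy numbers by
   least squares *with an intercept*, weighted by peak mass. The intercept
   is deliberate: on the printed worked example — peaks (1.0, 1.97, 2.94,
   3.82, 4.67) against copy numbers 1–5 — the intercept model reproduces
   SSR 0.008 and R² 1.0, while the no-intercept variant gives SSR ≈ 0.022;
   the package treats that reproduction as a regression test. Mass
   weighting keeps small artifact peaks from dominating the residuals;
5. candidates are filtered and the main ploidy selected.

Selection needs care, because the candidate family is closed under scaling
and several *aliases* of the true ploidy p produce deceptively good
regressions:

* **Off-by-one aliases** (P = p ± 1). Scaling by P/p maps every level to
  (P/p)·CN, and for consecutive levels the rounded copy numbers all shift by
  the same ±1 — an exactly affine relation that the intercept absorbs, with
  SSR *smaller* than the truth's by (P/p)². These fits are rejected by
  requiring the peaks to be genuinely centered on integers: slope within
  0.15 of 1 and intercept within 0.5 of 0 (the affine alias has intercept
  ±P/p, at least 0.67 in magnitude).
* **Multiples** (P = k·p). These place all modes on integers with slope 1
  and intercept 0, and residuals scaled by k. Among plausible candidates the
  minimum-SSR candidate is found first; a smaller plausible *divisor* of it
  whose SSR is within the expected (best/P)² scaling (times 1.5) is then
  preferred — the automated version of reviewing ploidy multiples manually
  and taking the lowest plausible ploidy.
* **Resonances** (e.g. levels {3, 6, 9} under P = (2/3)·6 = 4 for a
  hexaploid cell). These are non-divisor candidates and compete on SSR,
  which the true candidate wins when the non-resonant levels are detected.

A fit with fewer than 3 peaks never passes: a line through two points is
saturated and carries no evidence about the scaling. A genuinely flat
genome therefore yields an inconclusive scan, and the workflow falls back
to ploidy 2 with a warning.

### Known limitation: high ploidies at high dispersion

At main ploidy p the per-bin ratio noise is multiplied by p when the signal
is scaled. With the default simulation dispersion of 0.1 (plus counting
noise), the smoothed per-bin values at p = 6 have a spread of ~0.25–0.3
copy-number units against a unit level spacing, and minor levels adjacent
to a dominant mode with ~6× their mass sit at the kernel-density resolution
limit: their modes are absorbed into the dominant peak's shoulders or
compressed toward it. When the odd levels of a hexaploid cell vanish this
way, the remaining even levels are *genuinely* consistent with ploidy 3,
and the lowest-plausible rule — like the manual review it automates —
answers 3. In our simulations (five levels, minor levels ~10% of the genome
each) main ploidies 2–4 are recovered in 100% of seeded replicates, while
ploidy 6 is recovered in roughly 60–90% depending on the random layout;
cells whose minor levels carry more genome, or lower-dispersion libraries,
recover reliably.

## Simulation model

The simulation module generates the study conditions at bin level:

* a GC landscape per chromosome as locally correlated noise (sd ≈ 0.07,
  correlation length ≈ 7 bins) clipped to [0.3, 0.7] — isochore-like
  variation on a scale *short* relative to copy-number segments. This
  matters: GC waves on the same scale as CNAs would confound the LOWESS
  correction in a way real genomes do not;
* per-bin weighted fragment counts from the site-density model
  `((1−gc)/2)^4` — the independence expectation for an AT-only 4-mer,
  monotone decreasing in GC, reproducing the anticorrelation between
  fragment counts and GC;
* a unimodal amplification-efficiency curve over GC shaped like a Beta(10,
  12) density (mode 0.45, scaled to maximum 1);
* per-bin expected weights proportional to `copyNumber ×
  weightedFragments × gcBias(gc) × mappability`, optionally multiplied by
  independent Gamma variates with coefficient of variation `dispersion`
  (default 0.1 — the paper-scale noise is known only empirically, through
  DLRS, so dispersion is a free parameter), and a multinomial draw of the
  configured total reads;
* panels of flat diploid cells sharing a systematic multiplicative factor on
  chosen "bad" bins;
* binomial thinning (`thinCounts()`) as the in-silico analog of read
  subsampling — thinning commutes with counting, which is property-tested;
* nested multi-resolution profiles by aggregating fine bins
  (`aggregateBins()`), so the same cell can be called at 100 kb through
  2 Mb;
* at small scale, full sequence-level genomes (`simulateReference()`) with
  planted TTAA sites at a GC-dependent rate, for exercising the digestion
  and annotation code against ground truth.

What the simulation does *not* emulate: sequencing error and alignment
artifacts, chimeric amplification products, duplicate reads, subclonal
mixtures, and real mappability structure (mappability is 1 except where
deliberately lowered). Passing tests on simulated data therefore validate
the statistical machinery under the stated biases, not robustness to every
artifact of real libraries.

## Evaluation

`rocAucWindows()` tiles the genome with fixed-size windows (windows with
less than half their length in usable bins are excluded), marks a window
altered when any reference call overlaps it (type and magnitude are not
compared), scores it with −log10 of the Wilcoxon p-value of its
longest-overlap segment (neutral windows score 0) and computes the AUC by
the rank statistic, making it invariant under monotone score transforms.
`specificityFlat()` counts windows touched by any call on an expected-flat
profile as false positives. `profileR2()` is the squared Pearson correlation
of per-window mean ratios between two profiles over shared usable windows.

## Operating points and reproduction

All thresholds surface in `pipelineConfig()` with their published defaults:
500-kb bins, LOWESS span 0.3 with 3 robustifying iterations, mappability
floor 0.85, blacklist flags 1.4/0.6 (strict), test level 0.01, uniformity
and coverage thresholds 0.2/0.6, 2% peak mass, R² filter 0.98, candidate
ploidies 2–8.

The problem sizes used by the test-suite and the acceptance script are
chosen to exercise the published operating points at desk scale: a
400-Mb four-chromosome genome (2,000 bins of 200 kb) with 400,000 reads for
the flat-sample specificity analysis; 1,000 bins of 500 kb with 500,000
reads for the uniformity metrics; one aberrant cell with 12 planted CNAs
over ~35% of the genome, simulated at 3.5 million reads, thinned to 200,000
and recalled at 100 kb–2 Mb resolutions for the subsampling ROC analysis;
and the same deep cell against a 1-million-read thinning for profile
stability. A worked example:

```{r example}
bins <- simulateBinAnnotations(c(chr1 = 100e6, chr2 = 100e6,
                                 chr3 = 100e6, chr4 = 100e6),
                               binSize = 500000, seed = 101)
regions <- GRanges(c("chr1", "chr2", "chr3"),
                   IRanges(c(20e6, 40e6, 10e6) + 1, width = c(20e6, 25e6, 15e6)),
                   copyNumber = c(3L, 1L, 4L))
cn <- binCopyNumbers(bins, regions)
cell <- simulateCellCounts(bins, cn, totalReads = 500000, seed = 102)
result <- runCell(cell, bins, cellId = "demo")
result$mainPloidy
result$qc$uniformity
calls(result$callset)
```

The repository-level script `scripts/acceptance.R` re-simulates these
conditions from a single seed and writes the four headline numbers
(flat-sample specificity, uniformity, 60%-of-mean coverage fraction, and
minimum multi-resolution AUC) as JSON.
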
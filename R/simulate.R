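#' Default simulation bias models
#'
#' `siteDensityModel()` maps GC fraction to the expected density (per bp) of
#' TTAA restriction sites: the independence expectation `((1-gc)/2)^4`, a
#' monotone decreasing function of GC, reproducing the anticorrelation
#' between fragment counts and GC content that restriction-based genome
#' representation shows. `gcBiasBeta()` is a unimodal amplification/sequencing
#' efficiency curve over GC, shaped like a Beta density and peaking at GC
#' 0.45, scaled to maximum 1.
#'
#' @param gc GC fractions in `[0, 1]`.
#' @return Numeric vector of rates (sites per bp) or relative efficiencies.
#' @export
siteDensityModel <- function(gc) {
  ((1 - gc) / 2)^4
}

#' @rdname siteDensityModel
#' @param shape1,shape2 Beta shape parameters (defaults 10 and 12, mode 0.45).
#' @export
gcBiasBeta <- function(shape1 = 10, shape2 = 12) {
  mode <- (shape1 - 1) / (shape1 + shape2 - 2)
  peak <- dbeta(mode, shape1, shape2)
  function(gc) dbeta(pmin(pmax(gc, 0), 1), shape1, shape2) / peak
}

# smooth per-bin GC landscape for one chromosome: locally correlated noise
# (isochore-like, correlation length a few bins) around a genome-wide center,
# clipped to [0.3, 0.7]. GC must vary on a scale short relative to typical
# copy-number segments, or GC strata and copy-number states confound.
.gcLandscape <- function(nBins, center = 0.45, sdGC = 0.07, corBins = 7L) {
  k <- min(corBins, nBins - (1 - nBins %% 2))
  raw <- runningMean(rnorm(nBins, 0, sdGC * sqrt(max(k, 1))), k)
  pmin(pmax(center + raw, 0.3), 0.7)
}

#' Simulate an annotated bin table without sequence
#'
#' Generates the static genome model at bin resolution: a smooth GC landscape
#' in `[0.3, 0.7]`, per-bin weighted fragment counts derived from the
#' GC-dependent restriction-site density (so fragment counts anticorrelate
#' with GC), and unit mappability except for an optional set of low-mappability
#' bins. This is the desk-scale stand-in for annotating real bins from a
#' reference sequence, and is what the count simulator consumes.
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param binSize Bin size in bp.
#' @param lowMappBins Integer indices of bins to assign mappability 0.4
#'   (default none).
#' @param seed Optional seed for reproducibility.
#' @return An annotated bin `GRanges` (columns `gc`, `nFraction`,
#'   `mappability`, `masked`, `weightedFragments`).
#' @export
simulateBinAnnotations <- function(chromLengths, binSize = 500000L,
                                   lowMappBins = integer(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- makeBins(chromLengths, binSize)
  ch <- .chromFactor(b)
  gc <- unlist(lapply(levels(ch), function(cc) .gcLandscape(sum(ch == cc))),
               use.names = FALSE)
  mcols(b)$gc <- gc
  mcols(b)$nFraction <- 0
  mapp <- rep(1, length(b))
  mapp[lowMappBins] <- 0.4
  mcols(b)$mappability <- mapp
  mcols(b)$masked <- FALSE
  mcols(b)$weightedFragments <- binSize * siteDensityModel(gc)
  b
}

#' Per-bin copy numbers from planted alteration regions
#'
#' Assigns each bin the copy number of the planted region containing its
#' midpoint, or `basePloidy` outside all regions.
#'
#' @param bins Bin `GRanges`.
#' @param regions `GRanges` with a `copyNumber` metadata column (may be
#'   empty).
#' @param basePloidy Background copy number (default 2).
#' @return Integer vector of per-bin copy numbers.
#' @export
binCopyNumbers <- function(bins, regions, basePloidy = 2L) {
  cn <- rep(as.integer(basePloidy), length(bins))
  if (length(regions)) {
    mid <- (start(bins) + end(bins)) %/% 2L
    mids <- GRanges(as.character(seqnames(bins)), IRanges(mid, mid))
    ov <- suppressWarnings(findOverlaps(mids, regions, select = "first"))
    hit <- !is.na(ov)
    cn[hit] <- as.integer(regions$copyNumber[ov[hit]])
  }
  cn
}

#' Simulate one cell's binned read counts
#'
#' The expected weight of bin *b* is proportional to
#' `copyNumber(b) * weightedFragments(b) * gcBias(gc_b) * mappability(b)`;
#' with `dispersion > 0` each bin's weight is additionally multiplied by an
#' independent Gamma variate with mean 1 and coefficient of variation
#' `dispersion` (amplification over-dispersion), and `totalReads` reads are
#' then drawn multinomially over the bins.
#'
#' @param bins Annotated bin `GRanges` (see [simulateBinAnnotations()] or
#'   [annotateBins()] + [weightedFragmentCount()]).
#' @param copyNumber Integer vector of per-bin copy numbers, or a single
#'   value recycled (default 2, flat diploid).
#' @param totalReads Total reads to distribute.
#' @param gcBias Function mapping GC to relative efficiency (default
#'   [gcBiasBeta()]); `NULL` disables GC bias.
#' @param dispersion Gamma over-dispersion CV (default 0.1; 0 = clean
#'   multinomial).
#' @param seed Optional seed.
#' @return A [BinnedCounts-class].
#' @export
simulateCellCounts <- function(bins, copyNumber = 2L, totalReads = 500000L,
                               gcBias = gcBiasBeta(), dispersion = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(bins)
  cn <- rep_len(as.numeric(copyNumber), n)
  wf <- mcols(bins)$weightedFragments
  if (is.null(wf)) wf <- rep(1, n)
  gc <- mcols(bins)$gc
  bias <- if (is.null(gcBias)) rep(1, n) else gcBias(gc)
  mapp <- mcols(bins)$mappability
  if (is.null(mapp)) mapp <- rep(1, n)
  mapp[is.na(mapp)] <- 1
  lambda <- cn * wf * bias * mapp
  lambda[is.na(lambda)] <- 0
  if (all(lambda == 0)) stop("all bin weights are zero")
  if (dispersion > 0)
    lambda <- lambda * rgamma(n, shape = 1 / dispersion^2,
                              scale = dispersion^2)
  cnt <- as.integer(rmultinom(1, size = totalReads, prob = lambda))
  methods::new("BinnedCounts", counts = cnt,
               nAssigned = as.integer(totalReads), nDiscarded = 0L)
}

#' Simulate a panel of flat normal cells with systematically biased bins
#'
#' Each cell is a flat diploid profile; the bins listed in `badBins` carry a
#' shared multiplicative factor (e.g. 1.6 or 0.5), emulating the
#' systematically misbehaving genome regions a panel of normals is used to
#' detect. All other variation is independent per cell.
#'
#' @inheritParams simulateCellCounts
#' @param nCells Number of panel cells (>= 2).
#' @param badBins Integer indices of systematically biased bins.
#' @param badFactor Multiplicative factor for those bins (default 1.6).
#' @return List of [BinnedCounts-class], one per cell.
#' @export
simulateNormalPanel <- function(bins, nCells = 21L, totalReads = 500000L,
                                badBins = integer(0), badFactor = 1.6,
                                gcBias = gcBiasBeta(), dispersion = 0.1,
                                seed = NULL) {
  if (nCells < 2L) stop("need at least 2 panel cells")
  if (!is.null(seed)) set.seed(seed)
  n <- length(bins)
  fac <- rep(1, n)
  fac[badBins] <- badFactor
  # fold the systematic factor into a per-bin copy-number-like multiplier
  lapply(seq_len(nCells), function(i)
    simulateCellCounts(bins, copyNumber = 2 * fac, totalReads = totalReads,
                       gcBias = gcBias, dispersion = dispersion))
}

#' Binomial thinning of binned counts
#'
#' Keeps each read independently with probability `p`, which is distributed
#' identically to counting a `p * totalReads` sequencing run of the same cell
#' — the in-silico analog of random read subsampling.
#'
#' @param counts A [BinnedCounts-class].
#' @param p Retention probability in (0, 1].
#' @param seed Optional seed.
#' @return A thinned [BinnedCounts-class].
#' @export
thinCounts <- function(counts, p, seed = NULL) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cnt <- counts(counts)
  thin <- rbinom(length(cnt), cnt, p)
  methods::new("BinnedCounts", counts = as.integer(thin),
               nAssigned = as.integer(sum(thin)),
               nDiscarded = counts@nDiscarded)
}

#' Aggregate bins and counts to a coarser resolution
#'
#' Merges each run of `factor` consecutive bins within a chromosome into one
#' bin (a trailing incomplete group is dropped): counts and weighted fragment
#' counts are summed, GC, mappability and N fraction averaged. Simulating at
#' the finest resolution and aggregating gives nested multi-resolution
#' profiles of the same cell.
#'
#' @param bins Annotated bin `GRanges`.
#' @param counts A [BinnedCounts-class] aligned with `bins`.
#' @param factor Integer number of fine bins per coarse bin.
#' @return List with elements `bins` and `counts`.
#' @export
aggregateBins <- function(bins, counts, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(list(bins = bins, counts = counts))
  ch <- .chromFactor(bins)
  cnt <- counts(counts)
  pieces <- lapply(levels(ch), function(cc) {
    idx <- which(ch == cc)
    k <- length(idx) %/% factor
    if (k == 0L) return(NULL)
    idx <- idx[seq_len(k * factor)]
    grp <- rep(seq_len(k), each = factor)
    agg <- function(v, f) as.numeric(tapply(v[idx], grp, f))
    data.frame(chrom = cc,
               start = agg(start(bins), min), end = agg(end(bins), max),
               gc = agg(mcols(bins)$gc, mean),
               nFraction = agg(mcols(bins)$nFraction, mean),
               mappability = agg(mcols(bins)$mappability, mean),
               weightedFragments = agg(mcols(bins)$weightedFragments, sum),
               count = agg(cnt, sum))
  })
  d <- do.call(rbind, pieces)
  b <- GRanges(d$chrom, IRanges(d$start, d$end),
               gc = d$gc, nFraction = d$nFraction,
               mappability = d$mappability,
               masked = d$nFraction > 0.5,
               weightedFragments = d$weightedFragments,
               seqlengths = seqlengths(bins))
  cnt2 <- as.integer(d$count)
  list(bins = b,
       counts = methods::new("BinnedCounts", counts = cnt2,
                             nAssigned = as.integer(sum(cnt2)),
                             nDiscarded = counts@nDiscarded +
                               counts@nAssigned - as.integer(sum(cnt2))))
}

# sample base characters with a given GC fraction
.sampleBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a reference genome with GC-dependent restriction-site density
#'
#' Builds chromosome sequences bin by bin: bases are drawn to match a smooth
#' target GC landscape, accidental TTAA occurrences are destroyed, and TTAA
#' sites are planted at a Poisson rate given by [siteDensityModel()] applied
#' to the bin's target GC (scaled by `siteRateScale`), so the planted site
#' count per chromosome is known exactly and per-bin fragment counts
#' anticorrelate with GC.
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp;
#'   sequence simulation is intended for small toy genomes).
#' @param binSize Bin size in bp.
#' @param siteRateScale Multiplier on the site-density model (default 1).
#' @param seed Optional seed.
#' @return List with `sequences` (a `DNAStringSet`), `bins` (bin `GRanges`
#'   with the target `gcTarget` column), `sitesPerChrom` (named integer) and
#'   `sitesPerBin` (integer vector aligned with `bins`).
#' @export
simulateReference <- function(chromLengths, binSize = 10000L,
                              siteRateScale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- makeBins(chromLengths, binSize)
  ch <- .chromFactor(b)
  gcT <- unlist(lapply(levels(ch), function(cc) .gcLandscape(sum(ch == cc))),
                use.names = FALSE)
  site <- c("T", "T", "A", "A")

  seqs <- character(length(chromLengths))
  names(seqs) <- names(chromLengths)
  sitesPerBin <- integer(length(b))
  for (cc in levels(ch)) {
    idx <- which(ch == cc)
    L <- as.integer(chromLengths[[cc]])
    bases <- character(L)
    planted <- integer(0) # 1-based site start positions on the chromosome
    for (i in idx) {
      s0 <- start(b)[i] - 1L # 0-based bin start
      w <- width(b)[i]
      rate <- siteRateScale * siteDensityModel(gcT[i])
      nSites <- rpois(1, rate * w)
      nSites <- min(nSites, floor(w / 8)) # keep planting feasible
      # non-site bases compensate for the AT-only planted sites
      gcAdj <- min(0.95, gcT[i] * w / max(1, w - 4 * nSites))
      bases[(s0 + 1):(s0 + w)] <- .sampleBases(w, gcAdj)
      if (nSites > 0) {
        # non-overlapping positions with >= 4 bp spacing inside the bin
        pos <- sort(sample.int(w - 3L, nSites * 3))
        pos <- pos[c(TRUE, diff(pos) >= 4)][seq_len(nSites)]
        pos <- pos[!is.na(pos)]
        for (p in pos) bases[s0 + p + 0:3] <- site
        planted <- c(planted, s0 + pos)
        sitesPerBin[i] <- length(pos)
      }
    }
    # remainder after the last complete bin
    tailStart <- if (length(idx)) end(b)[idx[length(idx)]] else 0L
    if (tailStart < L)
      bases[(tailStart + 1):L] <- .sampleBases(L - tailStart, 0.45)
    # destroy accidental TTAA occurrences not at planted positions,
    # mutating only bases outside planted site intervals
    sq <- paste(bases, collapse = "")
    inPlanted <- logical(L)
    for (p in planted) inPlanted[p + 0:3] <- TRUE
    for (iter in seq_len(20)) {
      occ <- start(matchPattern("TTAA", Biostrings::DNAString(sq)))
      extra <- setdiff(occ, planted)
      if (!length(extra)) break
      if (iter == 20L) stop("could not realize the requested site layout")
      for (p in extra) {
        cand <- (p + 0:3)[!inPlanted[p + 0:3]]
        j <- cand[1]
        bases[j] <- if (runif(1) < 0.5) "C" else "G"
      }
      sq <- paste(bases, collapse = "")
    }
    seqs[[cc]] <- sq
  }
  mcols(b)$gcTarget <- gcT
  sites <- vapply(levels(ch), function(cc)
    sum(sitesPerBin[ch == cc]), integer(1))
  list(sequences = DNAStringSet(seqs), bins = b,
       sitesPerChrom = sites, sitesPerBin = sitesPerBin)
}

#' Emit read intervals matching binned counts
#'
#' Places `counts[i]` fixed-length reads uniformly at random inside bin `i`
#' (mapping quality 60), sufficient to exercise the binned counting rules.
#'
#' @param bins Bin `GRanges`.
#' @param counts A [BinnedCounts-class].
#' @param readLength Read length in bp (default 100).
#' @param seed Optional seed.
#' @return A `GRanges` of reads with a `mapq` column.
#' @export
simulateReadsFromCounts <- function(bins, counts, readLength = 100L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- counts(counts)
  tot <- sum(cnt)
  chrom <- rep(as.character(seqnames(bins)), cnt)
  lo <- rep(start(bins), cnt)
  hi <- rep(pmax(start(bins), end(bins) - readLength + 1L), cnt)
  st <- lo + floor(runif(tot) * (hi - lo + 1L))
  GRanges(chrom, IRanges(st, width = readLength), mapq = 60L)
}
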